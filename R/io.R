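# Data input, scale configuration, and report output.

#' Scale configuration
#'
#' Describes the questionnaire structure: which items form each subscale, the
#' number of response categories per item, coding direction, and per-scale
#' analysis options.
#'
#' @param items Data frame with columns `item`, `scale`, `m` and optionally
#'   `reverse` (logical: recode `x -> m + 1 - x` on input).
#' @param residual_covariances Named list (by scale) of item-pair character
#'   vectors given extra residual covariances in the measurement model.
#' @param two_item_strategy Named character vector (by scale):
#'   `"zero_residual_cov"`, `"equal_loadings"` or `"auto"` for two-item scales.
#' @param free_intercept Named character vector (by scale): for two-item
#'   scales, the item whose intercept may be freed if recalibration is found
#'   (the choice is statistically arbitrary and must be substantive).
#' @return A `scale_config`.
#' @export
scale_config <- function(items, residual_covariances = list(),
                         two_item_strategy = character(),
                         free_intercept = character()) {
  items <- as_tibble(items)
  need <- c("item", "scale", "m")
  if (!all(need %in% names(items))) {
    abort(paste("config items need columns:", paste(need, collapse = ", ")))
  }
  items$item <- as.character(items$item)
  if (anyDuplicated(items$item)) abort("every item must belong to exactly one scale")
  if (any(items$m < 2L)) abort("items need at least 2 response categories")
  if (!"reverse" %in% names(items)) items$reverse <- FALSE
  structure(list(
    items = items, residual_covariances = residual_covariances,
    two_item_strategy = two_item_strategy, free_intercept = free_intercept
  ), class = "scale_config")
}

#' @export
print.scale_config <- function(x, ...) {
  cat("<scale_config>\n")
  print(x$items %>% group_by(.data$scale) %>%
          summarise(items = paste(.data$item, collapse = ", "),
                    categories = paste(unique(.data$m), collapse = "/")), n = Inf)
  invisible(x)
}

config_items <- function(config, scale = NULL) {
  it <- config$items
  if (!is.null(scale)) {
    it <- filter(it, .data$scale == !!scale)
    if (!nrow(it)) abort(sprintf("no items in scale '%s'", scale))
  } else if (length(unique(it$scale)) > 1L) {
    abort("config has several scales; pass `scale = ` to pick one")
  }
  it
}

#' Read a subject-level longitudinal ordinal dataset
#'
#' Accepts a CSV path or data frame in long layout (`subject_id`, `occasion`,
#' `item`, `response`) or wide layout (one column per item x occasion, named
#' `"item@occasion"`). Validates categories against the configuration,
#' applies reverse coding, and returns the canonical wide tibble.
#'
#' @param x Path to a CSV file, or a data frame.
#' @param config A [scale_config()].
#' @param layout `"auto"`, `"long"` or `"wide"`.
#' @return Wide tibble: `subject` plus one integer column per item x occasion.
#' @export
read_ordinal_data <- function(x, config, layout = c("auto", "long", "wide")) {
  layout <- match.arg(layout)
  df <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(x)
  }
  long_cols <- c("subject_id", "occasion", "item", "response")
  if (layout == "auto") {
    layout <- if (all(long_cols %in% names(df))) "long" else "wide"
  }
  if (layout == "long") {
    missing_cols <- setdiff(long_cols, names(df))
    if (length(missing_cols)) {
      abort(paste("long layout needs columns:", paste(missing_cols, collapse = ", ")))
    }
    dup <- df %>% dplyr::count(.data$subject_id, .data$occasion, .data$item) %>%
      filter(.data$n > 1L)
    if (nrow(dup)) {
      abort(sprintf("duplicate record: subject %s, item %s, occasion %s",
                    dup$subject_id[1], dup$item[1], dup$occasion[1]))
    }
    unknown <- setdiff(unique(df$item), config$items$item)
    if (length(unknown)) {
      abort(paste("unknown item(s):", paste(unknown, collapse = ", ")))
    }
    wide <- df %>%
      mutate(var = paste0(.data$item, "@", .data$occasion)) %>%
      select("subject_id", "var", "response") %>%
      tidyr::pivot_wider(names_from = "var", values_from = "response") %>%
      rename(subject = "subject_id")
  } else {
    wide <- df
    if (!"subject" %in% names(wide)) {
      wide <- mutate(wide, subject = row_number(), .before = 1)
    }
  }
  # validate + reverse-code
  for (i in seq_len(nrow(config$items))) {
    it <- config$items$item[i]
    m <- config$items$m[i]
    for (occ in 1:2) {
      colname <- paste0(it, "@", occ)
      if (!colname %in% names(wide)) next
      v <- wide[[colname]]
      bad <- which(!is.na(v) & (v < 1 | v > m | v != round(v)))
      if (length(bad)) {
        abort(sprintf("response %s out of range 1..%d for %s at row %d",
                      format(v[bad[1]]), m, colname, bad[1]))
      }
      if (isTRUE(config$items$reverse[i])) {
        wide[[colname]] <- m + 1L - as.integer(v)
      } else {
        wide[[colname]] <- as.integer(v)
      }
    }
  }
  wide
}

#' Write an analysis report
#'
#' Serializes a `stage1_result` or `rs_detect` result to JSON or aligned text
#' with deterministic field order, values at 2-3 decimals and the
#' `*` (p < .05) / `**` (p < .01) star convention.
#'
#' @param result A `stage1_result` or `rs_detect` object.
#' @param path Output file path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "text")) {
  format <- match.arg(format)
  payload <- report_payload(result)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 8, pretty = TRUE,
                         na = "null")
  } else {
    writeLines(report_text(payload), path)
  }
  invisible(path)
}

report_payload <- function(result) {
  rnd <- function(df, k = 3) {
    df <- as.data.frame(df)
    for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], k)
    df
  }
  if (inherits(result, "stage1_result")) {
    rep1 <- result$report
    rep1$thresholds <- vapply(rep1$thresholds, function(t) {
      paste(sprintf("%.2f", unlist(t)), collapse = " ")
    }, character(1))
    list(
      kind = "stage1",
      n = result$n, alpha = result$alpha, alpha_star = result$alpha_star,
      excluded = as.list(result$excluded),
      stage1 = rnd(rep1, 2)
    )
  } else if (inherits(result, "rs_detect")) {
    c(report_payload(result$stage1)[-1],
      list(
        kind = "detect",
        fit = rnd(result$fit_table, 3),
        shifts = rnd(as.data.frame(result$findings), 3),
        true_change = rnd(as.data.frame(result$true_change), 3),
        decomposition = rnd(as.data.frame(result$decomposition %>%
                                            select(-"sd_diff")), 2)
      ))
  } else {
    abort("write_report understands stage1_result and rs_detect objects")
  }
}

report_text <- function(payload) {
  out <- c(sprintf("== %s report (N = %d) ==", payload$kind, payload$n), "")
  for (nm in setdiff(names(payload), c("kind", "n"))) {
    x <- payload[[nm]]
    out <- c(out, paste0("-- ", nm, " --"))
    if (is.data.frame(x)) {
      out <- c(out, utils::capture.output(print.data.frame(x, row.names = FALSE)))
    } else {
      out <- c(out, paste(unlist(x), collapse = " "))
    }
    out <- c(out, "")
  }
  out
}
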