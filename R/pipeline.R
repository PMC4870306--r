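# End-to-end response-shift analysis for one subscale: Stage 1, measurement
# and no-response-shift models, iterative shift search, true change and the
# decomposition of change.

#' Detect response shifts and estimate true change
#'
#' Runs the full two-stage procedure for one subscale: the Stage-1 analysis
#' ([run_stage1()]); the Stage-2 measurement model (factor means 0, variances 1
#' at both occasions) and no-response-shift model (invariant intercepts and
#' loadings, occasion-1 factor fixed); the gated greedy search for shifts
#' ([search_shifts()]); and Step 4 ([true_change()], [decompose_change()]).
#' Single-item scales get the Stage-1 analysis only. Items with Stage-1
#' recalibration stay in the model with free intercepts/loadings but are
#' excluded from the invariance constraints, the candidate set, and change
#' interpretation.
#'
#' @inheritParams run_stage1
#' @param alpha_stop Stopping level of the iterative search (defaults to
#'   `alpha`).
#' @param estimator Passed to [fit_sem()].
#' @param include_theta Also constrain and search residual variances
#'   (nonuniform recalibration).
#' @param bound_theta Passed to [fit_sem()].
#' @return An `rs_detect` object (or the bare `stage1_result` for single-item
#'   scales).
#' @export
detect_response_shift <- function(data, config, scale = NULL, alpha = 0.05,
                                  alpha_stop = alpha,
                                  estimator = c("auto", "wls", "dwls", "uls"),
                                  include_theta = FALSE, bound_theta = FALSE,
                                  rmsea_cutoff = 0.1, acov = TRUE,
                                  method = c("two_step", "ml")) {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  cfg <- config_items(config, scale)
  scale_name <- unique(cfg$scale)

  stage1 <- run_stage1(data, config, scale = scale, alpha = alpha,
                       rmsea_cutoff = rmsea_cutoff, acov = acov, method = method)
  if (nrow(cfg) < 2L) {
    message(sprintf("scale '%s' has a single item: Stage 1 analyses only", scale_name))
    return(stage1)
  }

  items <- cfg$item
  dich_items <- cfg$item[cfg$m == 2L]
  opt <- function(x, name) if (!is.null(x) && name %in% names(x)) x[[name]] else NULL
  rescov <- opt(config$residual_covariances, scale_name) %||% list()
  if (length(rescov) && !is.list(rescov)) rescov <- list(rescov)

  meas_spec <- build_model(items, residual_covariances = rescov,
                           dichotomous_items = dich_items)
  two_item <- length(items) == 2L
  if (two_item) {
    strategy <- opt(config$two_item_strategy, scale_name) %||% "auto"
    meas_spec <- two_item_identification(meas_spec, strategy)
  }
  meas_spec <- identify_model(meas_spec, "measurement")
  meas_fit <- fit_sem(meas_spec, stage1$moments, estimator, bound_theta = bound_theta)

  ns_spec <- build_model(items, residual_covariances = rescov,
                         dichotomous_items = dich_items)
  if (two_item) {
    strategy_used <- meas_fit$spec$two_item_strategy
    ns_spec <- two_item_identification(ns_spec, strategy_used)
  }
  ns_spec <- identify_model(ns_spec, "no_response_shift",
                            except_items = stage1$excluded,
                            constrain_theta = include_theta)
  if (length(dich_items)) {
    ns_spec <- dichotomous_adaptation(ns_spec, dich_items)
  }
  if (two_item) {
    ns_spec$free_intercept <- opt(config$free_intercept, scale_name)
  }
  ns_fit <- fit_sem(ns_spec, stage1$moments, estimator, bound_theta = bound_theta)

  search <- search_shifts(ns_fit, meas_fit, alpha_stop = alpha_stop,
                          include_theta = include_theta)
  if (two_item && !nrow(search$findings) && !is.null(search$global) &&
      is.finite(search$global$p) && search$global$p < alpha_stop &&
      is.null(ns_spec$free_intercept)) {
    warn(paste("two-item scale shows response shift but no `free_intercept` choice was",
               "configured; with two items the choice of which intercept to free is",
               "statistically arbitrary and must be substantive"))
  }
  final <- search$final

  fit_table <- bind_rows(
    mutate(glance(meas_fit), model = "measurement", .before = 1),
    mutate(glance(ns_fit), model = "no_response_shift", .before = 1),
    if (nrow(search$findings)) mutate(glance(final), model = "response_shift", .before = 1)
  ) %>% select("model", "estimator", "chisq", "df", "p",
               "rmsea", "rmsea_lo", "rmsea_hi", "ecvi", "ecvi_lo", "ecvi_hi")

  structure(list(
    scale = scale_name, stage1 = stage1,
    measurement_fit = meas_fit, no_shift_fit = ns_fit, final_fit = final,
    findings = search$findings, global = search$global,
    reconceptualization_items = search$reconceptualization_items,
    true_change = true_change(final),
    decomposition = decompose_change(final),
    fit_table = fit_table, alpha = alpha, alpha_stop = alpha_stop
  ), class = "rs_detect")
}

#' @export
print.rs_detect <- function(x, ...) {
  cat(sprintf("<rs_detect> scale '%s' (%d items, N = %d)\n",
              x$scale, length(x$stage1$items), x$stage1$n))
  cat("\nModel fit:\n")
  print(x$fit_table, n = Inf)
  if (!is.null(x$global)) {
    cat(sprintf("\nGlobal response-shift test: p = %.4f\n", x$global$p))
  }
  if (nrow(x$findings)) {
    cat("\nShifts (in order of inclusion):\n")
    print(x$findings, n = Inf)
  } else {
    cat("\nNo response shifts detected.\n")
  }
  cat("\nTrue change in the common factor:\n")
  print(x$true_change)
  cat("\nDecomposition of change:\n")
  print(x$decomposition %>%
          select("item", "d_modeled", "d_recalibration", "d_reprioritization",
                 "d_true", "stars", "interpretable"), n = Inf)
  invisible(x)
}

#' @export
tidy.rs_detect <- function(x, ...) x$decomposition

#' @export
glance.rs_detect <- function(x, ...) {
  tibble(
    scale = x$scale, n = x$stage1$n, n_items = length(x$stage1$items),
    n_shifts = nrow(x$findings),
    true_change_d = x$true_change$d, true_change_p = x$true_change$p
  )
}
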