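# Reference tables from a published two-wave SF-36 study of 437 cancer
# patients (HRQL measured before and ~4 weeks after the start of antineoplastic
# treatment), shipped as plain-text fixtures: item frequency distributions,
# Stage-1 estimates (thresholds in the standard identification; means/SDs in
# the alternative identification), Stage-2 fit statistics, and effect sizes of
# change.  Entries that are internally inconsistent in the printed source are
# stored as NA or flagged in the `note`/`excluded` columns.

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "ordshift", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' SF-36 reference tables
#'
#' Machine-readable copies of the published study tables used in examples and
#' tests: per-item frequency distributions at both occasions
#' (`sf36_item_frequencies()`), Stage-1 estimates — invariance tests,
#' thresholds, underlying-variable means/SDs and pre-post correlations
#' (`sf36_stage1_estimates()`), Stage-2 model fit and difference statistics
#' (`sf36_fit_statistics()`), and effect sizes of observed, true and
#' decomposed change (`sf36_change_effects()`).
#'
#' @return A tibble.
#' @name sf36_tables
NULL

#' @rdname sf36_tables
#' @export
sf36_item_frequencies <- function() read_fixture("sf36_item_frequencies.csv")

#' @rdname sf36_tables
#' @export
sf36_stage1_estimates <- function() read_fixture("sf36_stage1_estimates.csv")

#' @rdname sf36_tables
#' @export
sf36_fit_statistics <- function() read_fixture("sf36_fit_statistics.csv")

#' @rdname sf36_tables
#' @export
sf36_change_effects <- function() read_fixture("sf36_change_effects.csv")

#' @rdname sf36_tables
#' @param item Item identifier (e.g. `"24"`).
#' @param occasion 1 (baseline) or 2 (follow-up).
#' @export
sf36_margins <- function(item, occasion) {
  fr <- sf36_item_frequencies()
  row <- fr[fr$item == item & fr$occasion == occasion, ]
  if (!nrow(row)) abort(sprintf("no frequencies for item %s occasion %d", item, occasion))
  counts <- as.numeric(row[1, paste0("c", seq_len(row$m[1]))])
  setNames(counts, seq_along(counts))
}

#' @rdname sf36_tables
#' @export
sf36_scale_config <- function() {
  fr <- sf36_item_frequencies() %>% filter(.data$occasion == 1)
  scale_config(
    tibble(item = as.character(fr$item), scale = fr$scale, m = fr$m),
    residual_covariances = list(
      MH = list(c("26", "30")),
      PF = list(c("4", "5"), c("6", "7")),
      VT = list(c("29", "31"))
    ),
    two_item_strategy = c(BP = "zero_residual_cov", SF = "equal_loadings"),
    free_intercept = c(BP = "21")
  )
}
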