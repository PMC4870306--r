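# Chi-square based approximate-fit measures shared by both stages.
#
# RMSEA and ECVI (and their 90% confidence intervals) are derived from the
# noncentral chi-square distribution of the test statistic T: the bounds of
# the noncentrality parameter lambda are the values at which the observed T
# sits at the 95th / 5th percentile of chi2(df, lambda).  All indices use
# N - 1 as the sample-size multiplier.

#' Confidence bounds for the noncentrality parameter
#'
#' Solves `P(chi2(df, lambda_L) <= T) = 1 - (1 - level) / 2` and
#' `P(chi2(df, lambda_U) <= T) = (1 - level) / 2` for `lambda`, truncating at
#' zero.
#'
#' @param T Observed chi-square statistic (`>= 0`).
#' @param df Degrees of freedom (`>= 1`).
#' @param level Confidence level (default 0.90).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
noncentrality_ci <- function(T, df, level = 0.90) {
  stopifnot(T >= 0, df >= 1)
  a <- (1 - level) / 2
  lower <- .solve_ncp(T, df, 1 - a)
  upper <- .solve_ncp(T, df, a)
  c(lower = lower, upper = upper)
}

# Find lambda >= 0 with pchisq(T, df, ncp = lambda) = target (decreasing in
# lambda); 0 if even lambda = 0 is below target.
.solve_ncp <- function(T, df, target, tol = 1e-8) {
  if (pchisq(T, df, ncp = 0) <= target) return(0)
  hi <- max(2 * T, 1)
  while (pchisq(T, df, ncp = hi) > target) hi <- hi * 2
  uniroot(function(l) pchisq(T, df, ncp = l) - target,
          lower = 0, upper = hi, tol = tol)$root
}

#' Root-mean-square error of approximation
#'
#' `rmsea = sqrt(max(T - df, 0) / (df (N - 1)))` with confidence bounds from
#' the noncentrality interval. Values below 0.08 are conventionally read as
#' "reasonable" and below 0.05 as "close" approximate fit; Stage-1 pairwise
#' normality checks use a 0.1 cutoff.
#'
#' @param T Chi-square statistic.
#' @param df Degrees of freedom (`>= 1`).
#' @param N Sample size.
#' @param level Confidence level for the interval.
#' @return One-row tibble with `rmsea`, `rmsea_lo`, `rmsea_hi`.
#' @export
rmsea <- function(T, df, N, level = 0.90) {
  if (df < 1) abort("rmsea is undefined for a saturated model (df = 0)")
  lam <- noncentrality_ci(T, df, level)
  denom <- df * (N - 1)
  tibble(
    rmsea = sqrt(max(T - df, 0) / denom),
    rmsea_lo = sqrt(lam[["lower"]] / denom),
    rmsea_hi = sqrt(lam[["upper"]] / denom)
  )
}

#' Expected cross-validation index
#'
#' `ecvi = (T + 2 q) / (N - 1)` where `q` is the number of free parameters;
#' confidence bounds replace `T` by `lambda_b + df`.
#'
#' @inheritParams rmsea
#' @param q Number of free parameters.
#' @return One-row tibble with `ecvi`, `ecvi_lo`, `ecvi_hi`.
#' @export
ecvi <- function(T, df, q, N, level = 0.90) {
  lam <- noncentrality_ci(T, df, level)
  tibble(
    ecvi = (T + 2 * q) / (N - 1),
    ecvi_lo = (lam[["lower"]] + df + 2 * q) / (N - 1),
    ecvi_hi = (lam[["upper"]] + df + 2 * q) / (N - 1)
  )
}

#' All fit indices for one model
#'
#' @inheritParams ecvi
#' @return One-row tibble: `chisq`, `df`, `p`, RMSEA and ECVI with intervals.
#' @export
fit_indices <- function(T, df, q, N, level = 0.90) {
  if (df == 0) {
    return(tibble(
      chisq = T, df = 0L, p = NA_real_, rmsea = 0, rmsea_lo = 0, rmsea_hi = 0,
      ecvi = (T + 2 * q) / (N - 1), ecvi_lo = NA_real_, ecvi_hi = NA_real_,
      n = N, q = q, saturated = TRUE
    ))
  }
  bind_cols_one(
    tibble(chisq = T, df = as.integer(df), p = pchisq(T, df, lower.tail = FALSE)),
    rmsea(T, df, N, level),
    ecvi(T, df, q, N, level),
    tibble(n = N, q = q, saturated = FALSE)
  )
}

bind_cols_one <- function(...) {
  out <- do.call(cbind, lapply(list(...), as.data.frame))
  as_tibble(out)
}

#' Chi-square difference test with ECVI difference
#'
#' Compares a restricted (nested) model to an unrestricted one:
#' `T_diff = T_r - T_u` on `df_r - df_u` degrees of freedom, with the
#' q-free ECVI difference `(T_diff - 2 df_diff) / (N - 1)` and its
#' noncentrality-based interval. An ECVI difference whose lower bound exceeds
#' zero indicates significantly worse approximate fit of the restricted model.
#'
#' @param T_r,df_r Statistic and df of the restricted model.
#' @param T_u,df_u Statistic and df of the unrestricted model (`df_u < df_r`).
#' @param N Sample size.
#' @param level Confidence level.
#' @return One-row tibble: `chisq_diff`, `df_diff`, `p`, `ecvi_diff` with
#'   bounds and a `worse_approx_fit` flag.
#' @export
chisq_diff_test <- function(T_r, df_r, T_u, df_u, N, level = 0.90) {
  if (df_r <= df_u) abort("models are not nested: df_r must exceed df_u")
  T_diff <- T_r - T_u
  if (T_diff < 0) {
    warn(sprintf("negative chi-square difference (%.3f) clipped at 0", T_diff))
    T_diff <- 0
  }
  df_diff <- df_r - df_u
  lam <- noncentrality_ci(T_diff, df_diff, level)
  lo <- (lam[["lower"]] - df_diff) / (N - 1)
  tibble(
    chisq_diff = T_diff, df_diff = as.integer(df_diff),
    p = pchisq(T_diff, df_diff, lower.tail = FALSE),
    ecvi_diff = (T_diff - 2 * df_diff) / (N - 1),
    ecvi_diff_lo = lo,
    ecvi_diff_hi = (lam[["upper"]] - df_diff) / (N - 1),
    worse_approx_fit = lo > 0
  )
}

#' Significance stars
#'
#' `**` for p < .01, `*` for p < .05, empty otherwise.
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
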