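# Maximum-likelihood polychoric / tetrachoric correlation from a contingency
# table, and the likelihood-ratio tests of underlying bivariate (trivariate)
# normality built on it.
#
# The multinomial log-likelihood of an m1 x m2 table under a discretized
# bivariate normal is sum_ij n_ij log pi_ij(thresholds, rho); the saturated
# log-likelihood is sum n_ij log(n_ij / N) (empty cells contribute 0).

RHO_CAP <- 0.999

multinom_sat_loglik <- function(counts) {
  counts <- as.numeric(counts)
  N <- sum(counts)
  nz <- counts > 0
  sum(counts[nz] * log(counts[nz] / N))
}

# Ordered-threshold parameterization: first value free, increments log-scaled.
thr_to_par <- function(t) c(t[1], if (length(t) > 1L) log(diff(t)))
par_to_thr <- function(p) {
  if (length(p) == 1L) return(p)
  cumsum(c(p[1], exp(p[-1])))
}

# Deterministic start for rho: Pearson correlation of category midpoints.
table_start_rho <- function(tab) {
  m1 <- nrow(tab); m2 <- ncol(tab)
  N <- sum(tab)
  if (N == 0) return(0)
  i <- row(tab); j <- col(tab)
  mi <- sum(i * tab) / N; mj <- sum(j * tab) / N
  vi <- sum((i - mi)^2 * tab); vj <- sum((j - mj)^2 * tab)
  if (vi <= 0 || vj <= 0) return(0)
  r <- sum((i - mi) * (j - mj) * tab) / sqrt(vi * vj)
  max(min(r, 0.95), -0.95)
}

margin_start_thr <- function(margin) {
  # pseudo-count keeps starts finite when categories are empty
  p <- (cumsum(margin) + 0.5) / (sum(margin) + 1)
  qnorm(pmin(pmax(p[-length(p)], 1e-5), 1 - 1e-5))
}

# exact standard-normal quantiles of a margin's cumulative proportions,
# guarded against empty categories
margin_qnorm_thresholds <- function(margin) {
  m <- length(margin)
  cum <- cumsum(margin)[-m] / sum(margin)
  cum <- pmin(pmax(cum, 1e-6), 1 - 1e-6)
  if (any(diff(cum) <= 0)) cum <- cummax(cum + seq_along(cum) * 1e-9)
  qnorm(cum)
}

#' Polychoric (tetrachoric) correlation by maximum likelihood
#'
#' Fits a discretized bivariate normal to an `m1 x m2` contingency table:
#' thresholds for both margins and the correlation `rho` are estimated jointly
#' by maximizing the multinomial likelihood, unless standardized thresholds are
#' supplied as fixed (the two-step estimator used for cross-variable
#' correlations, where each variable's scale comes from its own longitudinal
#' fit).
#'
#' @param tab Matrix (or table) of non-negative counts, at least 2 x 2.
#' @param fixed Optional list with elements `t1`, `t2`: standardized threshold
#'   vectors held fixed, so only `rho` is estimated.
#' @param smooth Continuity correction added to every cell (default 0; the
#'   conventional option is 0.5 for tables with empty cells).
#' @param rho_cap Cap on `|rho|` (default 0.999); estimates at the cap are
#'   flagged as boundary solutions with a warning.
#' @return A `polychoric_fit` object: `rho`, thresholds, log-likelihoods, the
#'   likelihood-ratio statistic against the saturated multinomial with
#'   `df = m1 m2 - m1 - m2` (free-threshold fit), and RMSEA.
#' @export
polychoric <- function(tab, fixed = NULL, smooth = 0, rho_cap = RHO_CAP) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) abort("counts must be non-negative with positive total")
  m1 <- nrow(tab); m2 <- ncol(tab)
  if (m1 < 2L || m2 < 2L) abort("both variables need at least 2 categories")
  if (smooth > 0) tab <- tab + smooth
  N <- sum(tab)
  sat <- multinom_sat_loglik(tab)

  rmarg <- rowSums(tab); cmarg <- colSums(tab)
  degenerate <- sum(rmarg > 0) < 2L || sum(cmarg > 0) < 2L
  if (degenerate) {
    warn("degenerate table: all mass in one row or column; rho not identified")
    return(structure(list(
      rho = 0, thresholds1 = margin_start_thr(rmarg), thresholds2 = margin_start_thr(cmarg),
      loglik = sat, sat_loglik = sat, lr_stat = 0, df = m1 * m2 - m1 - m2,
      p = NA_real_, rmsea = NA_real_, n = N, fixed = !is.null(fixed),
      boundary = TRUE, convergence = 0L
    ), class = "polychoric_fit"))
  }

  nz <- tab > 0
  nll_cells <- function(P) -sum(tab[nz] * log(pmax(P[nz], 1e-300)))

  if (is.null(fixed)) {
    q1 <- m1 - 1L
    q2 <- m2 - 1L
    start <- c(thr_to_par(margin_start_thr(rmarg)), thr_to_par(margin_start_thr(cmarg)),
               atanh(table_start_rho(tab)))
    nll <- function(par) {
      t1 <- par_to_thr(par[seq_len(q1)])
      t2 <- par_to_thr(par[q1 + seq_len(q2)])
      r <- tanh(par[q1 + q2 + 1L])
      nll_cells(bvn_cell_probs(t1, t2, r))
    }
    opt <- optim(start, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    t1 <- par_to_thr(opt$par[seq_len(q1)])
    t2 <- par_to_thr(opt$par[q1 + seq_len(q2)])
    rho <- tanh(opt$par[q1 + q2 + 1L])
    conv <- opt$convergence
    ll <- -opt$value
  } else {
    t1 <- fixed$t1
    t2 <- fixed$t2
    f <- function(r) nll_cells(bvn_cell_probs(t1, t2, r))
    opt <- optimize(f, interval = c(-rho_cap, rho_cap), tol = 1e-9)
    rho <- opt$minimum
    conv <- 0L
    ll <- -opt$objective
  }

  boundary <- abs(rho) >= rho_cap - 1e-6
  if (boundary) {
    warn(sprintf("correlation estimate at boundary; capped at %.3f", sign(rho) * rho_cap))
    rho <- sign(rho) * rho_cap
  }
  lr <- max(2 * (sat - ll), 0)
  df <- m1 * m2 - m1 - m2
  structure(list(
    rho = rho, thresholds1 = t1, thresholds2 = t2,
    loglik = ll, sat_loglik = sat, lr_stat = lr, df = df,
    p = if (df > 0 && is.null(fixed)) pchisq(lr, df, lower.tail = FALSE) else NA_real_,
    rmsea = if (df > 0 && is.null(fixed)) sqrt(max(lr - df, 0) / (df * (N - 1))) else NA_real_,
    n = N, fixed = !is.null(fixed), boundary = boundary, convergence = conv
  ), class = "polychoric_fit")
}

#' @export
print.polychoric_fit <- function(x, ...) {
  cat(sprintf("<polychoric_fit> rho = %.4f (N = %d%s)\n", x$rho, round(x$n),
              if (x$fixed) ", fixed thresholds" else ""))
  if (!x$fixed && x$df > 0) {
    cat(sprintf("  LR test of bivariate normality: chisq(%d) = %.3f, p = %.3f, RMSEA = %.3f\n",
                x$df, x$lr_stat, x$p, x$rmsea))
  }
  invisible(x)
}

#' @export
glance.polychoric_fit <- function(x, ...) {
  tibble(rho = x$rho, loglik = x$loglik, lr_stat = x$lr_stat, df = x$df,
         p = x$p, rmsea = x$rmsea, n = x$n, boundary = x$boundary)
}

#' Likelihood-ratio test of underlying bivariate normality
#'
#' Tests whether an observed two-way table is consistent with a discretized
#' bivariate normal (thresholds free): `lr = 2 (saturated - model)` on
#' `m1 m2 - m1 - m2` df. Not applicable when that df is zero or negative
#' (e.g., a 2 x 2 table); dichotomous variables are tested in triplets with
#' [tvn_test()] instead. Approximate fit is judged by RMSEA against a cutoff.
#'
#' @inheritParams polychoric
#' @param rmsea_cutoff RMSEA value above which the assumption is rejected
#'   (default 0.1).
#' @param alpha Significance level for the exact test.
#' @param method `"two_step"` (thresholds from the margins, correlation by ML —
#'   the classical workflow) or `"ml"` (all parameters by joint ML).
#' @return One-row tibble: `df`, `lr_stat`, `p`, `rmsea`, `applicable`,
#'   `bvn_ok` (RMSEA criterion), `reject_exact`.
#' @export
bvn_test <- function(tab, rmsea_cutoff = 0.1, alpha = 0.05, smooth = 0,
                     method = c("two_step", "ml")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  m1 <- nrow(tab); m2 <- ncol(tab)
  df <- m1 * m2 - m1 - m2
  if (df <= 0) {
    return(tibble(df = df, lr_stat = NA_real_, p = NA_real_, rmsea = NA_real_,
                  applicable = FALSE, bvn_ok = NA, reject_exact = NA))
  }
  if (method == "two_step") {
    if (smooth > 0) tab <- tab + smooth
    N <- sum(tab)
    fit <- polychoric(tab, fixed = list(t1 = margin_qnorm_thresholds(rowSums(tab)),
                                        t2 = margin_qnorm_thresholds(colSums(tab))))
    lr <- fit$lr_stat
    p <- pchisq(lr, df, lower.tail = FALSE)
    rms <- sqrt(max(lr - df, 0) / (df * (N - 1)))
  } else {
    fit <- polychoric(tab, smooth = smooth)
    lr <- fit$lr_stat; p <- fit$p; rms <- fit$rmsea
  }
  tibble(df = df, lr_stat = lr, p = p, rmsea = rms,
         applicable = TRUE, bvn_ok = rms <= rmsea_cutoff,
         reject_exact = p < alpha)
}

#' Bonferroni-corrected level for the pairwise normality battery
#'
#' With `n` items at two occasions there are `2 n^2 - n` variable pairs, so the
#' per-test level is `alpha / (2 n^2 - n)`.
#'
#' @param alpha Family-wise level.
#' @param n_items Number of items (not variables).
#' @return Per-test significance level.
#' @export
bonferroni_alpha <- function(alpha, n_items) {
  alpha / (2 * n_items^2 - n_items)
}

#' Trivariate-normality test for dichotomous triplets
#'
#' For three dichotomous variables a 2 x 2 x 2 table has 7 free proportions and
#' the discretized trivariate normal uses 3 thresholds + 3 correlations, giving
#' a 1-df likelihood-ratio test of underlying trivariate normality.
#'
#' @param arr 2 x 2 x 2 array of counts.
#' @param alpha Significance level.
#' @return One-row tibble with the three correlations, `lr_stat`, `df = 1`,
#'   `p`, `rmsea` and a boundary flag.
#' @export
tvn_test <- function(arr, alpha = 0.05) {
  arr <- as.array(arr)
  if (!all(dim(arr) == 2L)) abort("tvn_test expects a 2 x 2 x 2 table of counts")
  N <- sum(arr)
  if (N <= 0) abort("empty table")
  sat <- multinom_sat_loglik(arr)

  marg <- list(
    apply(arr, 1, sum), apply(arr, 2, sum), apply(arr, 3, sum)
  )
  start_thr <- vapply(marg, function(mg) qnorm(pmin(pmax((mg[1] + 0.5) / (N + 1), 1e-5), 1 - 1e-5)),
                      numeric(1))
  nz <- arr > 0
  nll <- function(par) {
    thr <- par[1:3]
    r <- tanh(par[4:6])
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- r[1]
    R[1, 3] <- R[3, 1] <- r[2]
    R[2, 3] <- R[3, 2] <- r[3]
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6) return(1e10 - 1e6 * min(ev))
    P <- tvn_cell_probs_fast(thr, r)
    -sum(arr[nz] * log(pmax(P[nz], 1e-300)))
  }
  opt <- optim(c(start_thr, atanh(c(0.1, 0.1, 0.1))), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  r <- tanh(opt$par[4:6])
  boundary <- any(abs(r) >= RHO_CAP)
  if (boundary) {
    warn("a correlation estimate is at the boundary (structural zeros?)")
    r <- pmin(pmax(r, -RHO_CAP), RHO_CAP)
  }
  lr <- max(2 * (sat + opt$value), 0)
  tibble(
    rho_12 = r[1], rho_13 = r[2], rho_23 = r[3],
    thresholds = list(opt$par[1:3]),
    lr_stat = lr, df = 1L, p = pchisq(lr, 1, lower.tail = FALSE),
    rmsea = sqrt(max(lr - 1, 0) / (N - 1)),
    n = N, boundary = boundary, reject_exact = pchisq(lr, 1, lower.tail = FALSE) < alpha
  )
}

# 2x2x2 cell probabilities by inclusion-exclusion: one trivariate CDF call,
# three bivariate and three univariate terms.
tvn_cell_probs_fast <- function(thr, r) {
  a <- thr[1]; b <- thr[2]; c <- thr[3]
  F1 <- pnorm(a); F2 <- pnorm(b); F3 <- pnorm(c)
  F12 <- pbvn(a, b, r[1])
  F13 <- pbvn(a, c, r[2])
  F23 <- pbvn(b, c, r[3])
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r[1]
  R[1, 3] <- R[3, 1] <- r[2]
  R[2, 3] <- R[3, 2] <- r[3]
  F123 <- as.numeric(mvtnorm::pmvnorm(
    lower = rep(-Inf, 3), upper = c(a, b, c), corr = R,
    algorithm = mvtnorm::TVPACK(abseps = 1e-10)
  ))
  p <- array(0, c(2, 2, 2))
  p[1, 1, 1] <- F123
  p[2, 1, 1] <- F23 - F123
  p[1, 2, 1] <- F13 - F123
  p[1, 1, 2] <- F12 - F123
  p[2, 2, 1] <- F3 - F13 - F23 + F123
  p[2, 1, 2] <- F2 - F12 - F23 + F123
  p[1, 2, 2] <- F1 - F12 - F13 + F123
  p[2, 2, 2] <- 1 - F1 - F2 - F3 + F12 + F13 + F23 - F123
  pmax(p, 0)
}
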