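# Longitudinal (two-occasion) Stage-1 model for a single item: one common
# threshold set, occasion-specific mean and SD of the underlying variable, and
# the pre-post polychoric correlation, estimated jointly by full ML on the
# pre x post contingency table (or on the two marginal distributions when the
# joint table is unavailable).
#
# Identification (standard parameterization): mu1 + mu2 = 0, sd1^2 + sd2^2 = 2.
# Dichotomous items: sd fixed at 1 at both occasions, only the mean moves.

# Internal engine. free_idx frees the given threshold positions across
# occasions (occasion 2 gets an additive offset); free_all frees the whole
# threshold set (then margins are standard normal at both occasions).
.fit_longitudinal <- function(tab = NULL, margins = NULL, free_idx = integer(0),
                              free_all = FALSE, smooth = 0) {
  joint <- !is.null(tab)
  if (joint) {
    tab <- as.matrix(tab)
    if (nrow(tab) != ncol(tab)) abort("pre x post table must be square (same categories)")
    if (smooth > 0) tab <- tab + smooth
    m <- nrow(tab)
    marg1 <- rowSums(tab)
    marg2 <- colSums(tab)
    N <- sum(tab)
  } else {
    marg1 <- as.numeric(margins[[1]])
    marg2 <- as.numeric(margins[[2]])
    if (length(marg1) != length(marg2)) abort("margins must have the same number of categories")
    m <- length(marg1)
    N <- (sum(marg1) + sum(marg2)) / 2
  }
  if (m < 2L) abort("need at least 2 categories")

  # collapse categories empty at both occasions (keeps thresholds identified)
  collapse_map <- seq_len(m)
  empty <- which(marg1 + marg2 == 0)
  if (length(empty)) {
    warn(sprintf("categories empty at both occasions collapsed into a neighbour: %s",
                 paste(empty, collapse = ", ")))
    keep <- setdiff(seq_len(m), empty)
    collapse_map <- vapply(seq_len(m), function(i) {
      lower <- keep[keep <= i]
      if (length(lower)) max(lower) else min(keep)
    }, integer(1))
    grp <- match(collapse_map, keep)
    if (joint) {
      tab <- rowsum(t(rowsum(tab, grp)), grp)
      marg1 <- rowSums(tab); marg2 <- colSums(tab)
    } else {
      marg1 <- as.numeric(rowsum(marg1, grp))
      marg2 <- as.numeric(rowsum(marg2, grp))
    }
    m <- length(keep)
  }

  dich <- m == 2L
  q_thr <- m - 1L
  pooled_thr <- margin_start_thr(marg1 + marg2)

  if (free_all) {
    if (!joint) abort("free thresholds per occasion require the joint table")
    fit <- polychoric(tab, smooth = 0)
    return(list(
      scale = underlying_scale(list(fit$thresholds1, fit$thresholds2),
                               c(0, 0), c(1, 1), "standard"),
      rho = fit$rho, loglik = fit$loglik, sat_loglik = fit$sat_loglik,
      lr_stat = fit$lr_stat, df = fit$df, n_par = 2L * q_thr + 1L,
      n = fit$n, m = m, collapse_map = collapse_map, convergence = fit$convergence
    ))
  }

  n_free <- length(free_idx)
  # parameter vector: thr_par (q_thr), offsets (n_free), mu, [v], [z]
  unpack <- function(par) {
    i <- 0L
    thr <- par_to_thr(par[i + seq_len(q_thr)]); i <- i + q_thr
    off <- if (n_free) par[i + seq_len(n_free)] else numeric(0); i <- i + n_free
    mu2 <- par[i + 1L]; i <- i + 1L
    if (dich) {
      s1 <- 1; s2 <- 1
    } else {
      v <- par[i + 1L]; i <- i + 1L
      s1sq <- 2 * stats::plogis(v)
      s1 <- sqrt(s1sq); s2 <- sqrt(2 - s1sq)
    }
    z <- if (joint) par[i + 1L] else NA_real_
    thr2 <- thr
    if (n_free) thr2[free_idx] <- thr2[free_idx] + off
    list(thr1 = thr, thr2 = thr2, mu = c(-mu2, mu2), sd = c(s1, s2),
         rho = if (joint) tanh(z) else NA_real_)
  }
  if (joint) {
    nz <- tab > 0
    nll <- function(par) {
      p <- unpack(par)
      st1 <- (p$thr1 - p$mu[1]) / p$sd[1]
      st2 <- (p$thr2 - p$mu[2]) / p$sd[2]
      if (!all(is.finite(st1)) || !all(is.finite(st2)) || !is.finite(p$rho)) return(1e10)
      if (n_free && any(diff(st2) <= 0)) return(1e10)
      P <- bvn_cell_probs(st1, st2, p$rho)
      -sum(tab[nz] * log(pmax(P[nz], 1e-300)))
    }
    sat <- multinom_sat_loglik(tab)
  } else {
    nz1 <- marg1 > 0; nz2 <- marg2 > 0
    nll <- function(par) {
      p <- unpack(par)
      P1 <- norm_cell_probs((p$thr1 - p$mu[1]) / p$sd[1])
      P2 <- norm_cell_probs((p$thr2 - p$mu[2]) / p$sd[2])
      -sum(marg1[nz1] * log(pmax(P1[nz1], 1e-300))) -
        sum(marg2[nz2] * log(pmax(P2[nz2], 1e-300)))
    }
    sat <- multinom_sat_loglik(marg1) + multinom_sat_loglik(marg2)
  }

  start <- c(thr_to_par(pooled_thr), rep(0, n_free), 0,
             if (!dich) 0, if (joint) atanh(if (joint) table_start_rho(tab) else 0))
  opt <- optim(start, nll, method = "BFGS", control = list(maxit = 1000, reltol = 1e-12))
  p <- unpack(opt$par)
  n_par <- q_thr + n_free + 1L + (!dich) + joint
  ll <- -opt$value
  lr <- max(2 * (sat - ll), 0)
  df <- if (joint) (m^2 - 1L) - n_par else 2L * (m - 1L) - n_par
  list(
    scale = underlying_scale(p$thr1, p$mu, p$sd, "standard"),
    thresholds2 = p$thr2, rho = p$rho,
    loglik = ll, sat_loglik = sat, lr_stat = lr, df = df, n_par = n_par,
    n = N, m = m, collapse_map = collapse_map, convergence = opt$convergence
  )
}

# Two-step estimator of the longitudinal scale, mirroring the classical
# ordinal-SEM (PRELIS) workflow: thresholds are the standard-normal quantiles
# of the occasion-1 margin (occasion 1's underlying variable is the reference:
# mean 0, SD 1); the occasion-2 mean and SD are then ML given those thresholds;
# the pre-post correlation is ML given all margin parameters.
.fit_two_step <- function(tab = NULL, margins = NULL, smooth = 0) {
  joint <- !is.null(tab)
  if (joint) {
    tab <- as.matrix(tab)
    if (nrow(tab) != ncol(tab)) abort("pre x post table must be square (same categories)")
    if (smooth > 0) tab <- tab + smooth
    marg1 <- rowSums(tab); marg2 <- colSums(tab)
  } else {
    marg1 <- as.numeric(margins[[1]])
    marg2 <- as.numeric(margins[[2]])
    if (length(marg1) != length(marg2)) abort("margins must have the same number of categories")
  }
  m <- length(marg1)
  collapse_map <- seq_len(m)
  empty <- which(marg1 + marg2 == 0)
  if (length(empty)) {
    warn(sprintf("categories empty at both occasions collapsed into a neighbour: %s",
                 paste(empty, collapse = ", ")))
    keep <- setdiff(seq_len(m), empty)
    collapse_map <- vapply(seq_len(m), function(i) {
      lower <- keep[keep <= i]
      if (length(lower)) max(lower) else min(keep)
    }, integer(1))
    grp <- match(collapse_map, keep)
    if (joint) {
      tab <- rowsum(t(rowsum(tab, grp)), grp)
      marg1 <- rowSums(tab); marg2 <- colSums(tab)
    } else {
      marg1 <- as.numeric(rowsum(marg1, grp))
      marg2 <- as.numeric(rowsum(marg2, grp))
    }
    m <- length(keep)
  }
  dich <- m == 2L
  N1 <- sum(marg1)
  cum <- cumsum(marg1)[-m] / N1
  cum <- pmin(pmax(cum, 1e-6), 1 - 1e-6)
  if (any(diff(cum) <= 0)) {
    # category empty at occasion 1 only: keep thresholds ordered
    warn("tied cumulative proportions at occasion 1; thresholds separated by epsilon")
    cum <- cummax(cum + seq_along(cum) * 1e-9)
  }
  thr <- qnorm(cum)

  ll1 <- sum(marg1[marg1 > 0] * log(norm_cell_probs(thr)[marg1 > 0]))
  if (dich) {
    p2 <- min(max(marg2[1] / sum(marg2), 1e-6), 1 - 1e-6)
    mu2 <- thr[1] - qnorm(p2)
    s2 <- 1
    ll2 <- sum(marg2[marg2 > 0] * log(norm_cell_probs(thr - mu2)[marg2 > 0]))
  } else {
    nz2 <- marg2 > 0
    nll2 <- function(par) {
      P <- norm_cell_probs((thr - par[1]) / exp(par[2]))
      -sum(marg2[nz2] * log(pmax(P[nz2], 1e-300)))
    }
    o2 <- optim(c(0, 0), nll2, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    mu2 <- o2$par[1]
    s2 <- exp(o2$par[2])
    ll2 <- -o2$value
  }
  rho <- NA_real_
  ll <- ll1 + ll2
  sat <- multinom_sat_loglik(marg1) + multinom_sat_loglik(marg2)
  if (joint) {
    st1 <- thr
    st2 <- (thr - mu2) / s2
    nz <- tab > 0
    f <- function(r) -sum(tab[nz] * log(pmax(bvn_cell_probs(st1, st2, r)[nz], 1e-300)))
    opt <- optimize(f, interval = c(-RHO_CAP, RHO_CAP), tol = 1e-9)
    rho <- opt$minimum
    ll <- -opt$objective
    sat <- multinom_sat_loglik(tab)
  }
  n_par <- (m - 1L) + 1L + (!dich) + joint
  list(
    scale = underlying_scale(thr, c(0, mu2), c(1, s2), "standard"),
    rho = rho, loglik = ll, sat_loglik = sat, lr_stat = max(2 * (sat - ll), 0),
    df = (if (joint) m^2 - 1L else 2L * (m - 1L)) - n_par, n_par = n_par,
    n = if (joint) sum(tab) else (sum(marg1) + sum(marg2)) / 2,
    m = m, collapse_map = collapse_map, convergence = 0L
  )
}

# The occasion-1-referenced scale from the two-step estimator is re-identified
# into the standard parameterization (means summing to 0, squared SDs to 2).
.reference_to_standard <- function(scale) {
  b <- sqrt(2 / sum(scale$sds^2))
  a <- -b * mean(scale$means)
  underlying_scale(a + b * scale$thresholds, a + b * scale$means, b * scale$sds, "standard")
}

#' Longitudinal fit of a single item's underlying scale
#'
#' Fits one ordinal item observed at two occasions under a common threshold
#' set: thresholds, per-occasion mean and SD of the underlying normal
#' variable, and (when the pre x post table is supplied) the pre-post
#' polychoric correlation. Dichotomous items have both SDs fixed at 1. When
#' only the two marginal frequency distributions are available the same model
#' is fitted to the margins (no correlation).
#'
#' Two estimation flows are available. `"two_step"` (default) is the classical
#' ordinal-SEM workflow: thresholds are the standard-normal quantiles of the
#' occasion-1 margin, the occasion-2 mean and SD are ML given those
#' thresholds, and the correlation is ML given all margin parameters.
#' `"ml"` maximizes the joint multinomial likelihood over all parameters
#' simultaneously. Both are re-identified to the requested parameterization;
#' they agree asymptotically, and `"two_step"` matches the output of the
#' standard PRELIS-style longitudinal analysis.
#'
#' @param tab Square pre x post contingency table (occasion 1 in rows).
#' @param margins Alternative to `tab`: list of two marginal count vectors.
#' @param parameterization Identification in which the result is returned
#'   (see [reparameterize()]).
#' @param method `"two_step"` or `"ml"`.
#' @param smooth Continuity correction added to each cell of `tab`.
#' @return An `item_scale_fit`: the [underlying_scale()], `rho`, log-likelihood,
#'   LR statistic against the saturated multinomial, df, and a record of any
#'   category collapsing.
#' @export
fit_item_longitudinal <- function(tab = NULL, margins = NULL,
                                  parameterization = c("standard", "alternative"),
                                  method = c("two_step", "ml"),
                                  smooth = 0) {
  parameterization <- match.arg(parameterization)
  method <- match.arg(method)
  if (is.null(tab) && is.null(margins)) abort("supply either `tab` or `margins`")
  fit <- if (method == "two_step") {
    f <- .fit_two_step(tab = tab, margins = margins, smooth = smooth)
    f$ref_scale <- f$scale  # occasion-1-referenced raw estimates (acov uses these)
    f$scale <- .reference_to_standard(f$scale)
    f
  } else {
    f <- .fit_longitudinal(tab = tab, margins = margins, smooth = smooth)
    sc <- f$scale
    f$ref_scale <- underlying_scale(
      (sc$thresholds - sc$means[1]) / sc$sds[1],
      (sc$means - sc$means[1]) / sc$sds[1],
      sc$sds / sc$sds[1], "standard"
    )
    f
  }
  fit$method <- method
  if (parameterization == "alternative") {
    fit$scale <- reparameterize(fit$scale, "alternative")
  }
  structure(fit, class = "item_scale_fit")
}

#' @export
print.item_scale_fit <- function(x, ...) {
  cat("<item_scale_fit>\n")
  print(x$scale)
  if (!is.na(x$rho)) cat(sprintf("  pre-post rho: %.3f\n", x$rho))
  cat(sprintf("  loglik %.3f, LR %.3f on %d df (N = %d)\n",
              x$loglik, x$lr_stat, x$df, round(x$n)))
  invisible(x)
}

#' @export
glance.item_scale_fit <- function(x, ...) {
  tibble(rho = x$rho, loglik = x$loglik, lr_stat = x$lr_stat, df = x$df,
         n = x$n, m = x$m, convergence = x$convergence)
}

#' Test of threshold invariance across occasions
#'
#' Likelihood-ratio comparison, for one item's pre x post table, of the
#' equal-thresholds longitudinal model against the model with free thresholds
#' at each occasion (standard-normal margins). The difference has
#' `m - 3` degrees of freedom, so the test is applicable only for items with
#' at least four categories. A rejection indicates recalibration of the
#' response scale relative to the underlying variable.
#'
#' @param tab Square pre x post contingency table.
#' @param alpha Significance level for the decision.
#' @param level Confidence level for the ECVI difference interval.
#' @param smooth Continuity correction added to each cell.
#' @return One-row tibble: `applicable`, `chisq_diff`, `df_diff`, `p`,
#'   `ecvi_diff` with bounds, and `decision`
#'   (`"retain"` / `"reject"` / `"not_applicable"`).
#' @export
threshold_invariance_test <- function(tab, alpha = 0.05, level = 0.90, smooth = 0) {
  tab <- as.matrix(tab)
  m <- nrow(tab)
  if (m != ncol(tab)) abort("pre x post table must be square")
  if (m <= 3L) {
    return(tibble(applicable = FALSE, chisq_diff = NA_real_,
                  df_diff = if (m >= 2L) m - 3L else NA_integer_, p = NA_real_,
                  ecvi_diff = NA_real_, ecvi_diff_lo = NA_real_, ecvi_diff_hi = NA_real_,
                  decision = "not_applicable"))
  }
  con <- .fit_longitudinal(tab = tab, smooth = smooth)
  unc <- .fit_longitudinal(tab = tab, free_all = TRUE, smooth = smooth)
  N <- sum(tab)
  dt <- chisq_diff_test(con$lr_stat, con$df, unc$lr_stat, unc$df, N, level)
  tibble(applicable = TRUE, chisq_diff = dt$chisq_diff, df_diff = dt$df_diff,
         p = dt$p, ecvi_diff = dt$ecvi_diff, ecvi_diff_lo = dt$ecvi_diff_lo,
         ecvi_diff_hi = dt$ecvi_diff_hi,
         decision = if (dt$p < alpha) "reject" else "retain")
}

#' Test of a single threshold's invariance
#'
#' Frees only the threshold at `index` across occasions (1 df). With fewer
#' than five categories non-invariance cannot be attributed to a specific
#' threshold, so the test is not applicable.
#'
#' @inheritParams threshold_invariance_test
#' @param index Threshold position to free (1 to `m - 1`).
#' @return One-row tibble as in [threshold_invariance_test()], plus `index`
#'   and the estimated occasion-2 offset.
#' @export
individual_threshold_test <- function(tab, index, alpha = 0.05, level = 0.90,
                                      smooth = 0) {
  tab <- as.matrix(tab)
  m <- nrow(tab)
  if (m != ncol(tab)) abort("pre x post table must be square")
  if (m <= 4L) {
    return(tibble(index = as.integer(index), applicable = FALSE,
                  chisq_diff = NA_real_, df_diff = NA_integer_, p = NA_real_,
                  offset = NA_real_, decision = "not_applicable"))
  }
  if (index < 1L || index > m - 1L) abort("threshold index out of range")
  con <- .fit_longitudinal(tab = tab, smooth = smooth)
  part <- .fit_longitudinal(tab = tab, free_idx = as.integer(index), smooth = smooth)
  stat <- max(con$lr_stat - part$lr_stat, 0)
  tibble(index = as.integer(index), applicable = TRUE,
         chisq_diff = stat, df_diff = 1L,
         p = pchisq(stat, 1, lower.tail = FALSE),
         offset = part$thresholds2[index] - (if (part$scale$occasion_specific)
           part$scale$thresholds[[1]][index] else part$scale$thresholds[index]),
         decision = if (pchisq(stat, 1, lower.tail = FALSE) < alpha) "reject" else "retain")
}
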