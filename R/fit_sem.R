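# Weighted least squares fitting of the Stage-2 factor model to the Stage-1
# moments.  F(theta) = (s - sigma(theta))' V (s - sigma(theta)) with s the
# stacked means + lower-triangle covariances and V the inverse (or diagonal
# inverse) of the estimated asymptotic covariance of s; the minimum of F is
# itself the chi-square statistic.  With a diagonal weight (DWLS) the
# mean-adjusted (Satorra-Bentler type) statistic T * df / tr(U Gamma) is used.

#' Fit a longitudinal factor model to Stage-1 moments
#'
#' @param spec An identified `rs_model_spec` (see [build_model()],
#'   [identify_model()]).
#' @param moments A `moment_set` (see [assemble_moments()], [run_stage1()]).
#' @param estimator `"auto"` picks WLS with the full weight matrix when the
#'   asymptotic covariance of the moments is available and well-conditioned
#'   (condition number below 1e10), falling back to mean-adjusted DWLS, then to
#'   unweighted least squares (no test statistic) when no covariance exists.
#' @param mean_adjusted Use the mean-adjusted statistic under DWLS (default
#'   `TRUE` when DWLS is selected).
#' @param bound_theta Constrain residual variances to be non-negative instead
#'   of only warning about Heywood cases.
#' @param control Passed to [nlminb()].
#' @return A `sem_fit`: estimates with standard errors, the test statistic and
#'   df, RMSEA/ECVI with 90% intervals, and convergence metadata.
#' @export
fit_sem <- function(spec, moments, estimator = c("auto", "wls", "dwls", "uls"),
                    mean_adjusted = NULL, bound_theta = FALSE, control = list()) {
  estimator <- match.arg(estimator)
  if (is.null(spec$identified)) abort("identify the model before fitting (see identify_model())")
  if (!identical(spec$vars$var, moments$vars$var)) {
    if (!setequal(spec$vars$var, moments$vars$var)) {
      abort("model variables do not match the moment set")
    }
    # reorder moments to the spec's variable order
    ord <- match(spec$vars$var, moments$vars$var)
    perm <- moment_permutation(length(ord), ord)
    moments <- structure(list(
      vars = moments$vars[ord, ], mu = moments$mu[ord],
      sigma = moments$sigma[ord, ord], n = moments$n,
      acov = if (!is.null(moments$acov)) moments$acov[perm, perm] else NULL
    ), class = "moment_set")
  }
  if (identical(spec$two_item_strategy, "auto")) {
    return(.fit_two_item_auto(spec, moments, estimator, mean_adjusted, bound_theta, control))
  }

  s <- moment_vector(moments$mu, moments$sigma)
  N <- moments$n
  p <- nrow(spec$vars)
  acov <- moments$acov

  # drop variance moments that are identities of the parameterization
  # (dichotomous items: unit tetrachoric variances)
  keep <- seq_along(s)
  dv <- spec$derived_vars %||% character(0)
  if (length(dv)) {
    M <- matrix(0L, p, p)
    M[lower.tri(M, diag = TRUE)] <- seq_len(p * (p + 1) / 2)
    j <- match(dv, spec$vars$var)
    keep <- setdiff(keep, p + M[cbind(j, j)])
  }
  s <- s[keep]
  if (!is.null(acov)) acov <- acov[keep, keep, drop = FALSE]

  if (estimator == "auto") {
    if (!is.null(acov)) {
      kap <- tryCatch(kappa(acov, exact = FALSE), error = function(e) Inf)
      estimator <- if (is.finite(kap) && kap < 1e10) "wls" else "dwls"
    } else {
      estimator <- "uls"
    }
  }
  if (estimator %in% c("wls", "dwls") && is.null(acov)) {
    abort(sprintf("estimator %s needs the asymptotic covariance of the moments", estimator))
  }
  if (is.null(mean_adjusted)) mean_adjusted <- estimator == "dwls"

  V <- switch(estimator,
    wls = {
      Vi <- tryCatch(solve(acov), error = function(e) NULL)
      if (is.null(Vi)) {
        warn("weight matrix is singular; falling back to DWLS")
        estimator <- "dwls"
        diag(1 / diag(acov))
      } else Vi
    },
    dwls = diag(1 / diag(acov)),
    uls = diag(length(s))
  )

  spec <- .apply_start_values(spec, moments)
  cs <- compile_spec(spec)
  q <- length(cs$start)
  ltri <- lower.tri(matrix(0, p, p), diag = TRUE)
  fill <- cs$fill
  sig_vec <- function(theta) {
    m <- fill(theta)
    d <- as.vector(m$scale)
    mu <- d * as.vector(m$tau + m$lambda %*% m$kappa)
    sg <- (m$lambda %*% m$phi %*% t(m$lambda) + m$theta) * tcrossprod(d)
    c(mu, sg[ltri])[keep]
  }
  obj <- function(theta) {
    r <- s - sig_vec(theta)
    as.numeric(r %*% V %*% r)
  }
  # analytic Jacobian of the stacked implied moments:
  # mu = D (tau + Lambda kappa), Sigma = D (Lambda Phi Lambda' + Theta) D
  asg_info <- lapply(cs$asg, function(a) {
    nr <- switch(a$mat, lambda = p, tau = p, theta = p, scale = p, phi = 2L, kappa = 2L)
    list(mat = a$mat, row = (a$lin - 1L) %% nr + 1L,
         col = (a$lin - 1L) %/% nr + 1L, tidx = a$tidx)
  })
  n_mom <- p + p * (p + 1L) / 2L
  jac <- function(theta) {
    m <- fill(theta)
    d <- as.vector(m$scale)
    S <- m$lambda %*% m$phi %*% t(m$lambda) + m$theta
    PL <- m$lambda %*% m$phi  # p x K: (Lambda Phi)
    tk <- as.vector(m$tau + m$lambda %*% m$kappa)
    dd <- tcrossprod(d)
    J <- matrix(0, n_mom, q)
    for (a in asg_info) {
      dmu <- NULL
      dSig <- NULL
      if (a$mat == "tau") {
        dmu <- numeric(p); dmu[a$row] <- d[a$row]
      } else if (a$mat == "kappa") {
        dmu <- d * m$lambda[, a$row]
      } else if (a$mat == "lambda") {
        dmu <- numeric(p); dmu[a$row] <- d[a$row] * m$kappa[a$col]
        dS <- matrix(0, p, p)
        dS[a$row, ] <- dS[a$row, ] + PL[, a$col]
        dS[, a$row] <- dS[, a$row] + PL[, a$col]
        dSig <- dS * dd
      } else if (a$mat == "theta") {
        dS <- matrix(0, p, p)
        dS[a$row, a$col] <- 1
        dS[a$col, a$row] <- 1  # no-op when row == col
        dSig <- dS * dd
      } else if (a$mat == "phi") {
        dS <- if (a$row == a$col) {
          tcrossprod(m$lambda[, a$row])
        } else {
          tcrossprod(m$lambda[, a$row], m$lambda[, a$col]) +
            tcrossprod(m$lambda[, a$col], m$lambda[, a$row])
        }
        dSig <- dS * dd
      } else { # scale factor d_j
        j <- a$row
        dmu <- numeric(p); dmu[j] <- tk[j]
        dSig <- matrix(0, p, p)
        dSig[j, ] <- S[j, ] * d
        dSig[, j] <- dSig[, j] + d * S[, j]
      }
      if (!is.null(dmu)) J[seq_len(p), a$tidx] <- J[seq_len(p), a$tidx] + dmu
      if (!is.null(dSig)) {
        J[p + seq_len(n_mom - p), a$tidx] <- J[p + seq_len(n_mom - p), a$tidx] + dSig[ltri]
      }
    }
    J[keep, , drop = FALSE]
  }
  grad <- function(theta) {
    r <- s - sig_vec(theta)
    as.vector(-2 * t(jac(theta)) %*% (V %*% r))
  }
  if (bound_theta) {
    lower <- rep(-Inf, q)
    lower[match(theta_diag_groups(spec), cs$groups)] <- 0
    ctrl <- modifyList(list(rel.tol = 1e-12, iter.max = 500, eval.max = 1000), control)
    opt <- nlminb(cs$start, obj, gradient = grad, lower = lower, control = ctrl)
    theta <- opt$par
    Fhat <- opt$objective
    converged <- opt$convergence == 0
  } else {
    # damped Gauss-Newton: sigma(theta) is close to linear in theta, so a few
    # Jacobian evaluations suffice
    gn <- gauss_newton(cs$start, s, sig_vec, jac, V,
                       tol = control$rel.tol %||% 1e-12,
                       max_iter = control$iter.max %||% 200)
    theta <- gn$theta
    Fhat <- gn$value
    converged <- gn$converged
  }
  if (!converged) {
    warn(sprintf("fit did not converge cleanly (gradient norm %.2e)",
                 sqrt(sum(grad(theta)^2))))
  }
  df <- model_df(spec)
  Gamma <- acov
  Delta <- jac(theta)
  T_stat <- Fhat
  adjusted <- FALSE
  if (estimator %in% c("dwls", "uls") || mean_adjusted && estimator != "wls") {
    if (!is.null(Gamma) && mean_adjusted && df > 0) {
      VD <- V %*% Delta
      U <- V - VD %*% solve(t(Delta) %*% VD, t(VD))
      T_stat <- Fhat * df / sum(U * Gamma)  # tr(U Gamma)
      adjusted <- TRUE
    } else if (estimator == "uls") {
      T_stat <- NA_real_
    }
  }

  # sandwich standard errors
  se <- rep(NA_real_, q)
  vcov_theta <- NULL
  if (!is.null(Gamma)) {
    DVD <- crossprod(Delta, V %*% Delta)
    bread <- tryCatch(solve(DVD), error = function(e) NULL)
    if (!is.null(bread)) {
      meat <- crossprod(Delta, V %*% Gamma %*% V %*% Delta)
      vcov_theta <- bread %*% meat %*% bread
      se <- sqrt(pmax(diag(vcov_theta), 0))
    }
  }

  mats <- fill(theta)
  heywood <- any(diag(mats$theta)[!spec$vars$var %in% dv] < -1e-8)
  if (length(dv)) {
    j <- match(dv, spec$vars$var)
    d <- as.vector(mats$scale)[j]
    common <- diag(mats$lambda %*% mats$phi %*% t(mats$lambda))[j]
    heywood <- heywood || any(1 / d^2 - common < -1e-8)
  }
  if (heywood && !bound_theta) {
    warn("Heywood case: negative residual variance estimate(s); see `bound_theta`")
  }

  est <- tibble(group = cs$groups, estimate = theta, se = se)
  fitstats <- if (is.na(T_stat)) {
    tibble(chisq = NA_real_, df = as.integer(df), p = NA_real_,
           rmsea = NA_real_, rmsea_lo = NA_real_, rmsea_hi = NA_real_,
           ecvi = NA_real_, ecvi_lo = NA_real_, ecvi_hi = NA_real_,
           n = N, q = q, saturated = df == 0)
  } else {
    fit_indices(T_stat, df, q, N)
  }

  structure(list(
    spec = spec, theta = theta, groups = cs$groups, estimates = est,
    vcov = vcov_theta, matrices = mats,
    mu_hat = model_implied_moments(spec, theta)$mu,
    sigma_hat = model_implied_moments(spec, theta)$sigma,
    statistic = T_stat, df = df, fit = fitstats,
    estimator = if (adjusted) paste0(estimator, "+mean-adjusted") else estimator,
    converged = converged, heywood = heywood, moments = moments,
    F_min = Fhat
  ), class = "sem_fit")
}

# Damped Gauss-Newton minimizer of (s - sigma(theta))' V (s - sigma(theta)).
gauss_newton <- function(start, s, sig_vec, jac, V, tol = 1e-12, max_iter = 200) {
  theta <- start
  r <- s - sig_vec(theta)
  f <- as.numeric(r %*% V %*% r)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    J <- jac(theta)
    JV <- crossprod(J, V)
    g <- JV %*% r
    Hmat <- JV %*% J
    step <- tryCatch(solve(Hmat + diag(1e-10, ncol(J)), g),
                     error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(Hmat + diag(max(diag(Hmat)) * 1e-6 + 1e-8, ncol(J)), g)
    }
    lam <- 1
    repeat {
      cand <- theta + lam * as.vector(step)
      rc <- s - sig_vec(cand)
      fc <- as.numeric(rc %*% V %*% rc)
      if (is.finite(fc) && fc <= f + 1e-14) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- theta; rc <- r; fc <- f; break }
    }
    moved <- sqrt(sum((cand - theta)^2))
    df_rel <- abs(f - fc) / max(f, 1e-12)
    theta <- cand; r <- rc; f <- fc
    if (moved < 1e-10 || df_rel < tol) { converged <- TRUE; break }
  }
  list(theta = theta, value = f, converged = converged, iterations = it)
}

.apply_start_values <- function(spec, moments) {
  v <- diag(moments$sigma)
  for (i in seq_len(nrow(spec$vars))) {
    lab_t <- paste0("tau_", spec$vars$var[i])
    lab_th <- paste0("theta_", spec$vars$var[i])
    j <- which(spec$params$label == lab_t)
    spec$params$value[j] <- ifelse(spec$params$free[j], moments$mu[i], spec$params$value[j])
    j <- which(spec$params$label == lab_th)
    spec$params$value[j] <- ifelse(spec$params$free[j], v[i] / 2, spec$params$value[j])
  }
  spec
}

theta_diag_groups <- function(spec) {
  pt <- spec$params
  i <- pt$matrix == "theta" & pt$row == pt$col & pt$free
  unique(ifelse(is.na(pt$group[i]), pt$label[i], pt$group[i]))
}

# permutation of the stacked moment vector induced by a variable permutation
moment_permutation <- function(p, ord) {
  M <- matrix(0L, p, p)
  M[lower.tri(M, diag = TRUE)] <- seq_len(p * (p + 1) / 2)
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  Mp <- M[ord, ord]
  c(ord, p + Mp[lower.tri(Mp, diag = TRUE)])
}

.fit_two_item_auto <- function(spec, moments, estimator, mean_adjusted, bound_theta, control) {
  fits <- lapply(c("zero_residual_cov", "equal_loadings"), function(st) {
    sp <- spec
    sp$two_item_strategy <- NULL
    sp <- two_item_identification(sp, st)
    fit_sem(sp, moments, estimator, mean_adjusted, bound_theta, control)
  })
  Ts <- vapply(fits, function(f) ifelse(is.na(f$statistic), f$F_min, f$statistic), numeric(1))
  pick <- which.min(Ts)
  chosen <- fits[[pick]]
  chosen$two_item_auto <- tibble(
    strategy = c("zero_residual_cov", "equal_loadings"),
    statistic = Ts, chosen = seq_along(fits) == pick
  )
  message(sprintf("two-item identification: '%s' kept (statistic %.3f vs %.3f)",
                  c("zero_residual_cov", "equal_loadings")[pick], Ts[pick], Ts[-pick][1]))
  chosen
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> %s model, estimator %s%s\n",
              x$spec$identified, x$estimator, if (x$converged) "" else " (NOT converged)"))
  if (!is.na(x$statistic)) {
    cat(sprintf("  chisq(%d) = %.3f, p = %.3f | RMSEA %.3f [%.3f; %.3f]\n",
                x$df, x$statistic, x$fit$p, x$fit$rmsea, x$fit$rmsea_lo, x$fit$rmsea_hi))
  } else {
    cat(sprintf("  ULS discrepancy %.5f on %d df (no reference distribution)\n",
                x$F_min, x$df))
  }
  invisible(x)
}

#' @export
tidy.sem_fit <- function(x, ...) {
  pt <- x$spec$params
  g <- ifelse(is.na(pt$group), pt$label, pt$group)
  est <- setNames(x$theta, x$groups)
  ses <- setNames(x$estimates$se, x$groups)
  pt %>%
    mutate(
      group = g,
      estimate = ifelse(.data$free, est[g], .data$value),
      se = ifelse(.data$free, ses[g], NA_real_),
      statistic = .data$estimate / .data$se,
      p.value = 2 * pnorm(-abs(.data$statistic))
    ) %>%
    select("matrix", "row", "col", "label", "group", "free",
           "estimate", "se", "statistic", "p.value") %>%
    as_tibble()
}

#' @export
glance.sem_fit <- function(x, ...) {
  bind_cols_one(
    tibble(estimator = x$estimator, converged = x$converged, heywood = x$heywood),
    x$fit
  )
}
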