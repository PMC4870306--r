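# Seeded generator of subject-level longitudinal ordinal data from a known
# factor model + threshold structure, with injectable response shifts.  Every
# pipeline stage is testable against the generating truth without any external
# data.

#' Generator configuration
#'
#' Specifies the generating longitudinal factor model. The default mirrors a
#' mental-health-like subscale: 5 items with 6 response categories at 2
#' occasions, N = 437, loadings 0.7, unit factor variances with pre-post factor
#' correlation 0.6, residual variances chosen so the underlying variables have
#' unit variance, same-item residual correlations 0.3 across occasions, and
#' equally spaced thresholds (-1.5, -0.75, 0, 0.75, 1.5).
#'
#' @param n_subjects Number of subjects.
#' @param n_items Number of items.
#' @param m Response categories per item (scalar or vector).
#' @param loadings Matrix `n_items x 2` (per occasion) or scalar/vector.
#' @param intercepts Matrix `n_items x 2` or scalar/vector.
#' @param theta_diag Residual variances, `n_items x 2` or scalar/vector.
#' @param theta_cross Same-item cross-occasion residual covariances (scalar or
#'   vector).
#' @param phi 2 x 2 factor covariance matrix.
#' @param kappa Factor means, length 2.
#' @param thresholds List (per item) of lists (per occasion) of threshold
#'   vectors, or a single vector recycled everywhere.
#' @param seed Mandatory integer seed.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_subjects = 437, n_items = 5, m = 6,
                       loadings = 0.7, intercepts = 0,
                       theta_diag = NULL, theta_cross = 0.3,
                       phi = matrix(c(1, 0.6, 0.6, 1), 2),
                       kappa = c(0, 0), thresholds = NULL, seed) {
  if (missing(seed)) abort("a seed is mandatory for reproducibility")
  m <- rep_len(as.integer(m), n_items)
  as_mat <- function(x, default = NULL) {
    if (is.null(x)) x <- default
    if (is.matrix(x)) x else matrix(rep_len(x, n_items), n_items, 2)
  }
  L <- as_mat(loadings)
  Tau <- as_mat(intercepts)
  Th <- as_mat(theta_diag, default = 1 - L[, 1]^2 * phi[1, 1])
  Tc <- rep_len(theta_cross, n_items) * sqrt(Th[, 1] * Th[, 2])
  phi <- as.matrix(phi)
  if (any(eigen(phi, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("phi must be positive definite")
  }
  if (any(Th <= 0)) abort("residual variances must be positive")
  if (any(abs(Tc) >= sqrt(Th[, 1] * Th[, 2]))) abort("residual covariances too large")
  if (is.null(thresholds)) {
    thresholds <- lapply(seq_len(n_items), function(i) {
      th <- if (m[i] == 2L) 0 else seq(-1.5, 1.5, length.out = m[i] - 1L)
      list(th, th)
    })
  } else if (is.numeric(thresholds)) {
    thresholds <- lapply(seq_len(n_items), function(i) list(thresholds, thresholds))
  }
  for (i in seq_len(n_items)) {
    for (t in 1:2) {
      if (length(thresholds[[i]][[t]]) != m[i] - 1L) {
        abort(sprintf("item %d occasion %d: %d thresholds needed", i, t, m[i] - 1L))
      }
      if (m[i] > 2L && any(diff(thresholds[[i]][[t]]) <= 0)) {
        abort("thresholds must be strictly increasing")
      }
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_items = as.integer(n_items), m = m,
    loadings = L, intercepts = Tau, theta_diag = Th, theta_cross = Tc,
    phi = phi, kappa = as.numeric(kappa), thresholds = thresholds,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Inject a response shift into a generator configuration
#'
#' Offsets the occasion-2 copy of one parameter by `delta`: an intercept shift
#' emulates uniform recalibration, a loading shift reprioritization, a residual
#' variance shift nonuniform recalibration, a threshold shift Stage-1
#' recalibration, and a factor-mean shift true change.
#'
#' @param config A [sim_config()].
#' @param parameter `"intercept"`, `"loading"`, `"theta"`, `"threshold"`, or
#'   `"kappa"`.
#' @param item Item index (ignored for `"kappa"`).
#' @param delta Offset added at occasion 2.
#' @param index Threshold position (for `parameter = "threshold"`; default all).
#' @return The modified `sim_config`.
#' @export
inject_shift <- function(config, parameter = c("intercept", "loading", "theta",
                                               "threshold", "kappa"),
                         item = 1L, delta = 0, index = NULL) {
  parameter <- match.arg(parameter)
  if (parameter != "kappa" && (item < 1L || item > config$n_items)) {
    abort("unknown item index")
  }
  switch(parameter,
    intercept = config$intercepts[item, 2] <- config$intercepts[item, 2] + delta,
    loading = config$loadings[item, 2] <- config$loadings[item, 2] + delta,
    theta = config$theta_diag[item, 2] <- config$theta_diag[item, 2] + delta,
    threshold = {
      ix <- index %||% seq_along(config$thresholds[[item]][[2]])
      config$thresholds[[item]][[2]][ix] <- config$thresholds[[item]][[2]][ix] + delta
    },
    kappa = config$kappa[2] <- config$kappa[2] + delta
  )
  config
}

#' Simulate a subject-level dataset
#'
#' Draws, subject-major with a single seeded generator: factor scores
#' `(xi1, xi2) ~ N(kappa, phi)`, residuals from the 2n-dimensional residual
#' covariance, then `y* = tau + lambda xi + eps`, discretized by the per-item
#' per-occasion thresholds into categories `1..m`. The same seed yields an
#' identical dataset.
#'
#' @param config A [sim_config()].
#' @param ystar Also return the latent continuous responses (debug mode)?
#' @return Wide tibble `subject`, `"item_i@t"` columns; with `ystar = TRUE`
#'   the latent values are attached as attribute `"ystar"`.
#' @export
simulate_ordinal <- function(config, ystar = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  ni <- config$n_items
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  cp <- chol(config$phi)
  xi <- matrix(rnorm(n * 2), n, 2) %*% cp + matrix(config$kappa, n, 2, byrow = TRUE)
  # residual covariance: block per item
  eps <- matrix(0, n, 2 * ni)
  for (i in seq_len(ni)) {
    S <- matrix(c(config$theta_diag[i, 1], config$theta_cross[i],
                  config$theta_cross[i], config$theta_diag[i, 2]), 2)
    e <- matrix(rnorm(n * 2), n, 2) %*% chol(S)
    eps[, c(i, ni + i)] <- e
  }
  Y <- matrix(0, n, 2 * ni)
  X <- matrix(0L, n, 2 * ni)
  vars <- variable_grid(paste0("item_", seq_len(ni)))
  for (t in 1:2) {
    for (i in seq_len(ni)) {
      col <- (t - 1L) * ni + i
      y <- config$intercepts[i, t] + config$loadings[i, t] * xi[, t] + eps[, col]
      Y[, col] <- y
      X[, col] <- findInterval(y, config$thresholds[[i]][[t]]) + 1L
    }
  }
  out <- as_tibble(as.data.frame(X))
  names(out) <- vars$var
  out <- mutate(out, subject = row_number(), .before = 1)
  if (ystar) {
    colnames(Y) <- vars$var
    attr(out, "ystar") <- Y
  }
  out
}

#' Scale configuration matching a generator configuration
#'
#' @param config A [sim_config()].
#' @param scale Scale name for the generated items.
#' @return A [scale_config()] covering the generated items.
#' @export
sim_scale_config <- function(config, scale = "sim") {
  scale_config(tibble(
    item = paste0("item_", seq_len(config$n_items)),
    scale = scale, m = config$m
  ))
}

# Model-implied latent moments of the generator (debug / test oracle).
sim_implied_moments <- function(config) {
  ni <- config$n_items
  L <- matrix(0, 2 * ni, 2)
  for (t in 1:2) L[(t - 1) * ni + seq_len(ni), t] <- config$loadings[, t]
  tau <- c(config$intercepts[, 1], config$intercepts[, 2])
  Th <- diag(c(config$theta_diag[, 1], config$theta_diag[, 2]))
  for (i in seq_len(ni)) {
    Th[i, ni + i] <- Th[ni + i, i] <- config$theta_cross[i]
  }
  vars <- variable_grid(paste0("item_", seq_len(ni)))$var
  mu <- as.vector(tau + L %*% config$kappa)
  sigma <- L %*% config$phi %*% t(L) + Th
  names(mu) <- vars
  dimnames(sigma) <- list(vars, vars)
  list(mu = mu, sigma = sigma)
}
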