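# Bivariate/trivariate normal probabilities used throughout Stage 1.
#
# The bivariate CDF uses deterministic Gauss-Legendre quadrature on the
# Drezner-Wesolowsky identity
#   Phi2(h, k, rho) = Phi(h) Phi(k)
#     + (1 / 2pi) Int_0^asin(rho) exp(-(h^2 - 2 h k sin t + k^2) / (2 cos^2 t)) dt,
# which is smooth in t and vectorizes over (h, k).  For |rho| beyond 0.925 the
# integrand develops a boundary layer, so those (rare, near-boundary) cases are
# delegated to mvtnorm's deterministic TVPACK algorithm.

# Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigendecomposition.
gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
}

.bvn_gl <- gauss_legendre01(48L)

#' Standard bivariate normal CDF
#'
#' Lower-tail probability `P(X <= h, Y <= k)` for standard normal `(X, Y)` with
#' correlation `rho`, by deterministic quadrature. Vectorized over `h` and `k`;
#' `rho` is a scalar.
#'
#' @param h,k Numeric vectors of upper limits (recycled against each other);
#'   `-Inf`/`Inf` allowed.
#' @param rho Scalar correlation in `[-1, 1]`.
#' @return Numeric vector of probabilities.
#' @export
pbvn <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), abs(rho) <= 1)
  nn <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), nn)
  k <- rep_len(as.numeric(k), nn)
  if (rho == 0) {
    return(pnorm(h) * pnorm(k))
  }
  if (abs(rho) >= 1) {
    # Degenerate: Y = +/- X exactly.
    return(if (rho > 0) pnorm(pmin(h, k)) else pmax(pnorm(h) + pnorm(k) - 1, 0))
  }
  if (abs(rho) > 0.925) {
    return(.pbvn_tvpack(h, k, rho))
  }
  out <- pnorm(h) * pnorm(k)
  fin <- is.finite(h) & is.finite(k)
  # Infinite limits reduce to univariate or zero terms already captured above.
  if (any(fin)) {
    hf <- h[fin]
    kf <- k[fin]
    up <- asin(rho)
    t <- up * .bvn_gl$nodes
    w <- up * .bvn_gl$weights
    sint <- sin(t)
    cos2t <- cos(t)^2
    # outer over quadrature nodes: rows = obs, cols = nodes
    e <- exp(-(outer(hf^2 + kf^2, rep(1, length(t))) -
                 2 * outer(hf * kf, sint)) / (2 * rep(cos2t, each = length(hf))))
    out[fin] <- out[fin] + as.vector(e %*% w) / (2 * pi)
  }
  pmin(pmax(out, 0), 1)
}

# TVPACK (deterministic Gauss quadrature inside mvtnorm) for high correlations.
.pbvn_tvpack <- function(h, k, rho) {
  corr <- matrix(c(1, rho, rho, 1), 2L)
  vapply(seq_along(h), function(i) {
    if (h[i] == -Inf || k[i] == -Inf) return(0)
    if (h[i] == Inf && k[i] == Inf) return(1)
    if (h[i] == Inf) return(pnorm(k[i]))
    if (k[i] == Inf) return(pnorm(h[i]))
    as.numeric(mvtnorm::pmvnorm(
      lower = c(-Inf, -Inf), upper = c(h[i], k[i]), corr = corr,
      algorithm = mvtnorm::TVPACK(abseps = 1e-12)
    ))
  }, numeric(1))
}

# Rectangle (cell) probabilities of a bivariate normal over the grid defined by
# two standardized threshold vectors (without the implicit -Inf/Inf).
bvn_cell_probs <- function(t1, t2, rho) {
  a <- c(-Inf, t1, Inf)
  b <- c(-Inf, t2, Inf)
  m1 <- length(a)
  m2 <- length(b)
  Fg <- matrix(pbvn(rep(a, times = m2), rep(b, each = m1), rho), m1, m2)
  P <- Fg[-1, -1, drop = FALSE] - Fg[-m1, -1, drop = FALSE] -
    Fg[-1, -m2, drop = FALSE] + Fg[-m1, -m2, drop = FALSE]
  pmax(P, 0)
}

# Univariate cell probabilities for standardized thresholds.
norm_cell_probs <- function(t) {
  diff(c(0, pnorm(t), 1))
}

# Trivariate normal orthant-box probabilities on a 2x2x2 grid given three
# standardized thresholds and a 3x3 correlation matrix (TVPACK, deterministic).
tvn_cell_probs <- function(thr, R) {
  stopifnot(length(thr) == 3L, all(dim(R) == c(3L, 3L)))
  p <- array(0, c(2L, 2L, 2L))
  lims <- lapply(thr, function(d) list(c(-Inf, d), c(d, Inf)))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    lo <- c(lims[[1]][[i]][1], lims[[2]][[j]][1], lims[[3]][[k]][1])
    hi <- c(lims[[1]][[i]][2], lims[[2]][[j]][2], lims[[3]][[k]][2])
    p[i, j, k] <- as.numeric(mvtnorm::pmvnorm(
      lower = lo, upper = hi, corr = R,
      algorithm = mvtnorm::TVPACK(abseps = 1e-10)
    ))
  }
  pmax(p, 0)
}
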