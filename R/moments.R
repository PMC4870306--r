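# Stacking Stage-1 estimates into the mean vector and covariance matrix of the
# underlying variables (the input to Stage 2), and the asymptotic covariance
# of those stacked moment estimates (the WLS weight matrix).
#
# Variable order is occasion-major: item_1..item_n at occasion 1, then the same
# items at occasion 2.  The moment vector stacks the 2n means first, then the
# lower triangle (including the diagonal) of the covariance matrix,
# column-major.

variable_grid <- function(items, occasions = 2L) {
  tibble(
    occasion = rep(seq_len(occasions), each = length(items)),
    item = rep(as.character(items), occasions)
  ) %>%
    mutate(var = paste0(.data$item, "@", .data$occasion)) %>%
    select("var", "item", "occasion")
}

#' Assemble Stage-1 moments
#'
#' Builds the stacked mean vector and covariance matrix of the underlying
#' variables from per-item longitudinal scales and the cross-variable
#' polychoric correlations.
#'
#' @param scales Named list (by item) of [underlying_scale()] objects with two
#'   occasions.
#' @param rho_within Named numeric vector: pre-post correlation of each item.
#' @param rho_cross Tibble with columns `var1`, `var2`, `rho` for every
#'   cross-item variable pair (`var` labels are `"item@occasion"`), or a full
#'   correlation matrix with dimnames.
#' @param n Sample size attached to the moments.
#' @return A `moment_set`: variable table, `mu`, `sigma`, `n` and (initially
#'   `NULL`) the asymptotic covariance `acov` of the stacked moment vector.
#' @export
assemble_moments <- function(scales, rho_within, rho_cross, n) {
  items <- names(scales)
  vars <- variable_grid(items)
  p <- nrow(vars)
  mu <- numeric(p)
  sd <- numeric(p)
  for (i in seq_len(p)) {
    sc <- scales[[vars$item[i]]]
    mu[i] <- sc$means[vars$occasion[i]]
    sd[i] <- sc$sds[vars$occasion[i]]
  }
  R <- diag(p)
  dimnames(R) <- list(vars$var, vars$var)
  for (it in items) {
    R[paste0(it, "@1"), paste0(it, "@2")] <- R[paste0(it, "@2"), paste0(it, "@1")] <-
      rho_within[[it]]
  }
  if (is.matrix(rho_cross)) {
    cross <- which(outer(vars$item, vars$item, `!=`), arr.ind = TRUE)
    R[cross] <- rho_cross[vars$var, vars$var][cross]
  } else {
    for (k in seq_len(nrow(rho_cross))) {
      R[rho_cross$var1[k], rho_cross$var2[k]] <- rho_cross$rho[k]
      R[rho_cross$var2[k], rho_cross$var1[k]] <- rho_cross$rho[k]
    }
  }
  miss <- which(is.na(R), arr.ind = TRUE)
  if (nrow(miss)) {
    abort(paste0("missing correlation estimate for pair(s): ",
                 paste(unique(paste(vars$var[miss[, 1]], vars$var[miss[, 2]], sep = " x ")),
                       collapse = ", ")))
  }
  sigma <- R * tcrossprod(sd)
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warn(sprintf("assembled covariance matrix is not positive semidefinite (min eigenvalue %.2e)",
                 min(ev)))
  }
  names(mu) <- vars$var
  structure(list(vars = vars, mu = mu, sigma = sigma, n = n, acov = NULL),
            class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> %d variables (%d items x %d occasions), N = %s\n",
              nrow(x$vars), length(unique(x$vars$item)),
              max(x$vars$occasion), format(x$n)))
  cat("  acov:", if (is.null(x$acov)) "not set" else "available", "\n")
  invisible(x)
}

# Stacked moment vector: means, then lower triangle of sigma column-major.
moment_vector <- function(mu, sigma) {
  c(mu, sigma[lower.tri(sigma, diag = TRUE)])
}

moment_labels <- function(vars) {
  p <- nrow(vars)
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  c(paste0("mean_", vars$var),
    paste0("cov_", vars$var[idx[, 1]], "_", vars$var[idx[, 2]]))
}

# ---------------------------------------------------------------------------
# Asymptotic covariance of the stacked moments (two-step M-estimator sandwich).
#
# Every Stage-1 parameter solves an estimating equation with mean zero at the
# truth:
#   thresholds      Phi(delta_c) - P(x_{j,1} <= c) = 0          (occasion-1 margin)
#   mu2, sigma2     score of the occasion-2 margin likelihood   (given delta)
#   within-item rho score of the pre x post table likelihood    (given margins)
#   cross rho       score of the pairwise table likelihood      (given scales)
# With A = E[-d g / d theta'] (block lower-triangular in estimation order) and
# B = Cov(g), acov(theta) = A^-1 B A^-1' / N; the moment vector is a smooth
# function of theta, so acov(moments) follows by the delta method.
# ---------------------------------------------------------------------------

#' Asymptotic covariance of the stacked Stage-1 moments
#'
#' Computes the sandwich covariance of the Stage-1 moment estimates (means and
#' covariances of the underlying variables) from the subject-level data, by
#' treating the full two-step estimation flow as a stack of estimating
#' equations and applying the delta method to the parameter-to-moment map.
#' Used as the weight matrix of the Stage-2 WLS fit.
#'
#' @param stage1 A `stage1_result` (see [run_stage1()]) carrying the data it
#'   was fitted to.
#' @return The `stage1` object with `moments$acov` filled in
#'   (`length(s) x length(s)` matrix, `s` = stacked moments).
#' @export
estimate_acov <- function(stage1) {
  X <- stage1$data_matrix
  vars <- stage1$moments$vars
  items <- unique(vars$item)
  N <- nrow(X)

  # --- parameter bookkeeping -----------------------------------------------
  par <- list()     # current values by block
  blocks <- list()  # block descriptors
  free_thr <- setNames(vapply(items, function(it) isTRUE(stage1$fits[[it]]$free_thr),
                              logical(1)), items)
  for (it in items) {
    f <- stage1$fits[[it]]
    ref <- f$ref_scale  # occasion-1-referenced: mu1 = 0, sd1 = 1
    m <- f$m
    dich <- m == 2L
    if (free_thr[[it]]) {
      par[[paste0("thr_", it)]] <- ref$thresholds[[1]]
      blocks[[length(blocks) + 1L]] <- list(type = "thr", item = it, m = m)
      par[[paste0("thr2_", it)]] <- ref$thresholds[[2]]
      blocks[[length(blocks) + 1L]] <- list(type = "thr2", item = it, m = m)
    } else {
      par[[paste0("thr_", it)]] <- ref$thresholds
      blocks[[length(blocks) + 1L]] <- list(type = "thr", item = it, m = m)
      par[[paste0("loc_", it)]] <- if (dich) ref$means[2] else c(ref$means[2], ref$sds[2])
      blocks[[length(blocks) + 1L]] <- list(type = "loc", item = it, m = m, dich = dich)
    }
    par[[paste0("rho_", it)]] <- f$rho
    blocks[[length(blocks) + 1L]] <- list(type = "rho_within", item = it, m = m)
  }
  for (k in seq_len(nrow(stage1$cross))) {
    cr <- stage1$cross[k, ]
    par[[paste0("rho_", cr$var1, "_", cr$var2)]] <- cr$rho
    blocks[[length(blocks) + 1L]] <- list(type = "rho_cross", var1 = cr$var1, var2 = cr$var2)
  }
  theta <- unlist(par, use.names = FALSE)
  sizes <- lengths(par)
  offs <- cumsum(c(0L, head(sizes, -1L)))
  names(offs) <- names(par)
  Q <- length(theta)
  getp <- function(th, nm) th[offs[[nm]] + seq_len(sizes[[nm]])]

  m_of <- setNames(vapply(items, function(it) stage1$fits[[it]]$m, integer(1)), items)
  col_of <- setNames(seq_len(nrow(vars)), vars$var)
  item_col <- function(it, occ) col_of[[paste0(it, "@", occ)]]

  # standardized thresholds of a variable from the raw (referenced) parameters
  std_thr <- function(th, it, occ) {
    if (free_thr[[it]] && occ == 2L) return(getp(th, paste0("thr2_", it)))
    d <- getp(th, paste0("thr_", it))
    if (occ == 1L || free_thr[[it]]) return(d)
    loc <- getp(th, paste0("loc_", it))
    if (length(loc) == 1L) d - loc[1] else (d - loc[1]) / loc[2]
  }

  # --- per-cell scores, one block at a time ---------------------------------
  # each block's score matrix S has one row per cell of the table the block is
  # estimated from and one column per parameter of the block
  eps <- 1e-5
  block_scores <- function(b, th) {
    bl <- blocks[[b]]
    if (bl$type %in% c("thr", "thr2")) {
      d <- getp(th, paste0(if (bl$type == "thr") "thr_" else "thr2_", bl$item))
      S <- outer(seq_len(bl$m), seq_along(d), function(x, c) (x <= c) - pnorm(d[c]))
    } else if (bl$type == "loc") {
      d <- getp(th, paste0("thr_", bl$item))
      loc <- getp(th, paste0("loc_", bl$item))
      lmarg <- function(l) {
        st <- if (length(l) == 1L) d - l[1] else (d - l[1]) / l[2]
        log(pmax(norm_cell_probs(st), 1e-300))
      }
      S <- matrix(vapply(seq_along(loc), function(j) {
        e <- rep(0, length(loc)); e[j] <- eps
        (lmarg(loc + e) - lmarg(loc - e)) / (2 * eps)
      }, numeric(bl$m)), nrow = bl$m)
    } else if (bl$type == "rho_within") {
      it <- bl$item
      r <- getp(th, paste0("rho_", it))
      t1 <- std_thr(th, it, 1L)
      t2 <- std_thr(th, it, 2L)
      lp <- function(r) log(pmax(bvn_cell_probs(t1, t2, r), 1e-300))
      hi <- min(r + eps, RHO_CAP); lo <- max(r - eps, -RHO_CAP)
      S <- matrix(as.vector((lp(hi) - lp(lo)) / (hi - lo)), ncol = 1L)
    } else {
      meta1 <- vars[vars$var == bl$var1, ]; meta2 <- vars[vars$var == bl$var2, ]
      r <- getp(th, paste0("rho_", bl$var1, "_", bl$var2))
      t1 <- std_thr(th, meta1$item, meta1$occasion)
      t2 <- std_thr(th, meta2$item, meta2$occasion)
      lp <- function(r) log(pmax(bvn_cell_probs(t1, t2, r), 1e-300))
      hi <- min(r + eps, RHO_CAP); lo <- max(r - eps, -RHO_CAP)
      S <- matrix(as.vector((lp(hi) - lp(lo)) / (hi - lo)), ncol = 1L)
    }
    S
  }

  # observed cell proportions and subject -> cell index, computed once
  cell_index <- vector("list", length(blocks))
  p_obs <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    idx <- switch(bl$type,
      thr = X[, item_col(bl$item, 1L)],
      thr2 = ,
      loc = X[, item_col(bl$item, 2L)],
      rho_within = (X[, item_col(bl$item, 2L)] - 1L) * m_of[[bl$item]] +
        X[, item_col(bl$item, 1L)],
      rho_cross = {
        meta1 <- vars[vars$var == bl$var1, ]
        (X[, col_of[[bl$var2]]] - 1L) * m_of[[meta1$item]] + X[, col_of[[bl$var1]]]
      }
    )
    n_cells <- switch(bl$type,
      thr = , thr2 = , loc = bl$m,
      rho_within = m_of[[bl$item]]^2,
      rho_cross = {
        meta1 <- vars[vars$var == bl$var1, ]; meta2 <- vars[vars$var == bl$var2, ]
        m_of[[meta1$item]] * m_of[[meta2$item]]
      }
    )
    cell_index[[b]] <- idx
    p_obs[[b]] <- tabulate(idx, nbins = n_cells) / N
  }

  # per-subject score matrix (only needed once, for B)
  S0 <- do.call(cbind, lapply(seq_along(blocks), function(b) {
    block_scores(b, theta)[cell_index[[b]], , drop = FALSE]
  }))
  B <- crossprod(S0) / N  # mean scores are ~0 at the estimates

  # which estimating blocks depend on each parameter block
  block_parname <- vapply(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    switch(bl$type,
      thr = paste0("thr_", bl$item), thr2 = paste0("thr2_", bl$item),
      loc = paste0("loc_", bl$item), rho_within = paste0("rho_", bl$item),
      rho_cross = paste0("rho_", bl$var1, "_", bl$var2))
  }, character(1))
  block_deps <- lapply(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    dep_of_var <- function(v) {
      meta <- vars[vars$var == v, ]
      it <- meta$item
      if (meta$occasion == 1L || (free_thr[[it]] && meta$occasion == 1L)) {
        paste0("thr_", it)
      } else if (free_thr[[it]]) {
        paste0("thr2_", it)
      } else {
        c(paste0("thr_", it), paste0("loc_", it))
      }
    }
    switch(bl$type,
      thr = paste0("thr_", bl$item),
      thr2 = paste0("thr2_", bl$item),
      loc = c(paste0("thr_", bl$item), paste0("loc_", bl$item)),
      rho_within = unique(c(dep_of_var(paste0(bl$item, "@1")),
                            dep_of_var(paste0(bl$item, "@2")),
                            paste0("rho_", bl$item))),
      rho_cross = unique(c(dep_of_var(bl$var1), dep_of_var(bl$var2),
                           paste0("rho_", bl$var1, "_", bl$var2)))
    )
  })
  affected <- lapply(names(par), function(nm) {
    which(vapply(block_deps, function(d) nm %in% d, logical(1)))
  })
  names(affected) <- names(par)
  eq_rows <- lapply(names(par), function(nm) offs[[nm]] + seq_len(sizes[[nm]]))
  names(eq_rows) <- names(par)

  # A = -d gbar / d theta', exploiting the block dependency structure
  A <- matrix(0, Q, Q)
  hstep <- pmax(abs(theta), 0.1) * 1e-4
  gbar_blocks <- function(th, bs) {
    unlist(lapply(bs, function(b) as.vector(crossprod(p_obs[[b]], block_scores(b, th)))))
  }
  for (nm in names(par)) {
    bs <- affected[[nm]]
    rows <- unlist(eq_rows[block_parname[bs]])
    for (c in seq_len(sizes[[nm]])) {
      j <- offs[[nm]] + c
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + hstep[j]; tm[j] <- tm[j] - hstep[j]
      A[rows, j] <- -(gbar_blocks(tp, bs) - gbar_blocks(tm, bs)) / (2 * hstep[j])
    }
  }
  acov_theta <- tryCatch({
    Ai <- solve(A)
    Ai %*% B %*% t(Ai) / N
  }, error = function(e) {
    warn(paste("A-matrix of the estimating equations is singular:", conditionMessage(e)))
    NULL
  })
  if (is.null(acov_theta)) {
    stage1$acov_ill_conditioned <- TRUE
    return(stage1)
  }

  # --- delta method to the stacked moment vector ---------------------------
  # moments in the alternative parameterization, computed directly from the
  # raw (occasion-1-referenced) parameters
  p <- nrow(vars)
  cross_i <- match(stage1$cross$var1, vars$var)
  cross_j <- match(stage1$cross$var2, vars$var)
  cross_nm <- if (nrow(stage1$cross)) {
    paste0("rho_", stage1$cross$var1, "_", stage1$cross$var2)
  } else {
    character(0)
  }
  mom_fun <- function(th) {
    mu <- numeric(p); sdv <- numeric(p)
    R <- diag(p)
    for (it in items) {
      i1 <- item_col(it, 1L); i2 <- item_col(it, 2L)
      if (free_thr[[it]]) {
        for (occ in 1:2) {
          d <- getp(th, paste0(if (occ == 1L) "thr_" else "thr2_", it))
          a <- d[1]; bscl <- if (length(d) >= 2L) d[2] - d[1] else 1
          i <- if (occ == 1L) i1 else i2
          mu[i] <- -a / bscl; sdv[i] <- 1 / bscl
        }
      } else {
        d <- getp(th, paste0("thr_", it))
        loc <- getp(th, paste0("loc_", it))
        mu2 <- loc[1]; s2 <- if (length(loc) == 2L) loc[2] else 1
        a <- d[1]; bscl <- if (length(d) >= 2L) d[2] - d[1] else 1
        mu[i1] <- -a / bscl; mu[i2] <- (mu2 - a) / bscl
        sdv[i1] <- 1 / bscl; sdv[i2] <- s2 / bscl
      }
      r <- getp(th, paste0("rho_", it))
      R[i1, i2] <- R[i2, i1] <- r
    }
    for (k in seq_along(cross_nm)) {
      r <- getp(th, cross_nm[k])
      R[cross_i[k], cross_j[k]] <- R[cross_j[k], cross_i[k]] <- r
    }
    sigma <- R * tcrossprod(sdv)
    moment_vector(mu, sigma)
  }
  s0 <- mom_fun(theta)
  H <- matrix(0, length(s0), Q)
  for (j in seq_len(Q)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + hstep[j]; tm[j] <- tm[j] - hstep[j]
    H[, j] <- (mom_fun(tp) - mom_fun(tm)) / (2 * hstep[j])
  }
  acov <- H %*% acov_theta %*% t(H)
  acov <- (acov + t(acov)) / 2
  dimnames(acov) <- list(moment_labels(vars), moment_labels(vars))
  stage1$moments$acov <- acov
  kap <- tryCatch(kappa(acov, exact = FALSE), error = function(e) Inf)
  stage1$acov_ill_conditioned <- !is.finite(kap) || kap > 1e10
  if (stage1$acov_ill_conditioned) {
    warn("asymptotic covariance of the moments is ill-conditioned; DWLS fallback advised")
  }
  stage1
}
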