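# Longitudinal common-factor model for the underlying variables (Stage 2).
#
# Model: mu = D (tau + Lambda kappa), Sigma = D (Lambda Phi Lambda' + Theta) D,
# with one common factor per occasion, residual factors correlated across
# occasions for the same item, and (for dichotomous indicators) occasion-2
# scale factors D.  Every parameter carries a status: free, fixed(value), or
# member of an equality group.

#' Build a longitudinal common-factor model
#'
#' Constructs the (not yet identified) model specification for `n` items
#' measured at two occasions: one common factor per occasion, every indicator
#' loading on its occasion's factor, free intercepts and residual variances,
#' and same-item residual covariances across occasions. Additional residual
#' covariances between item pairs can be requested; such a modification frees
#' the full within- and cross-occasion covariance block of the pair.
#'
#' @param items Character vector of item identifiers (at least 2; single-item
#'   scales are analyzed with Stage 1 only).
#' @param residual_covariances Optional list of length-2 character vectors:
#'   item pairs given extra residual covariances.
#' @param dichotomous_items Items on a tetrachoric (unit-variance) scale: their
#'   residual variances are derived so the model-implied variances equal 1, and
#'   their variance moments are excluded from the fit.
#' @return An `rs_model_spec`.
#' @export
build_model <- function(items, residual_covariances = list(),
                        dichotomous_items = character()) {
  items <- as.character(items)
  if (length(items) < 2L) {
    abort("factor models need at least 2 items; analyze single-item scales with Stage 1 only")
  }
  if (!all(dichotomous_items %in% items)) abort("unknown dichotomous item(s)")
  vars <- variable_grid(items)
  p <- nrow(vars)
  n <- length(items)
  rows <- list()
  add <- function(matrix, row, col, free, value, group = NA_character_, label) {
    rows[[length(rows) + 1L]] <<- tibble(
      matrix = matrix, row = as.integer(row), col = as.integer(col),
      free = free, value = value, group = group, label = label
    )
  }
  for (i in seq_len(p)) {
    f <- vars$occasion[i]
    derived <- vars$item[i] %in% dichotomous_items
    add("lambda", i, f, TRUE, 0.7, label = paste0("lambda_", vars$var[i]))
    add("tau", i, 1L, TRUE, 0, label = paste0("tau_", vars$var[i]))
    if (!derived) {
      add("theta", i, i, TRUE, 0.5, label = paste0("theta_", vars$var[i]))
    }
    add("scale", i, 1L, FALSE, 1, label = paste0("scalefac_", vars$var[i]))
  }
  for (it in items) {
    i1 <- which(vars$var == paste0(it, "@1"))
    i2 <- which(vars$var == paste0(it, "@2"))
    add("theta", i2, i1, TRUE, 0.1, label = paste0("theta_", it, "@2_", it, "@1"))
  }
  for (pr in residual_covariances) {
    pr <- as.character(pr)
    if (!all(pr %in% items)) {
      abort(sprintf("unknown item(s) in residual covariance: %s",
                    paste(setdiff(pr, items), collapse = ", ")))
    }
    for (o1 in 1:2) for (o2 in 1:2) {
      i <- which(vars$var == paste0(pr[1], "@", o1))
      j <- which(vars$var == paste0(pr[2], "@", o2))
      add("theta", max(i, j), min(i, j), TRUE, 0.05,
          label = paste0("theta_", vars$var[max(i, j)], "_", vars$var[min(i, j)]))
    }
  }
  for (f in 1:2) {
    add("phi", f, f, TRUE, 1, label = paste0("phi_", f, "_", f))
    add("kappa", f, 1L, TRUE, 0, label = paste0("kappa_", f))
  }
  add("phi", 2L, 1L, TRUE, 0.5, label = "phi_2_1")
  structure(list(
    vars = vars, items = items, n_factors = 2L,
    params = bind_rows(rows), identified = NULL,
    dichotomous = length(dichotomous_items) > 0L,
    dichotomous_items = dichotomous_items,
    derived_vars = vars$var[vars$item %in% dichotomous_items]
  ), class = "rs_model_spec")
}

#' @export
print.rs_model_spec <- function(x, ...) {
  cat(sprintf("<rs_model_spec> %d items x 2 occasions (%d indicators)\n",
              length(x$items), nrow(x$vars)))
  cat(sprintf("  identification: %s | free parameters: %d | df: %d\n",
              if (is.null(x$identified)) "none" else x$identified,
              n_free_params(x), model_df(x)))
  invisible(x)
}

set_param <- function(spec, label, free = NULL, value = NULL, group = NULL) {
  i <- which(spec$params$label == label)
  if (!length(i)) abort(sprintf("unknown parameter label: %s", label))
  if (!is.null(free)) spec$params$free[i] <- free
  if (!is.null(value)) spec$params$value[i] <- value
  if (!is.null(group)) spec$params$group[i] <- group
  spec
}

#' Apply an identification scheme
#'
#' The `measurement` step fixes the common-factor means at zero and variances
#' at one at every occasion (no across-occasion constraints). The
#' `no_response_shift` step fixes only the occasion-1 factor mean and variance
#' and instead constrains intercepts and loadings to be equal across occasions
#' (occasion-2 factor mean and variance become free, identified through the
#' invariance constraints). Items listed in `except_items` (e.g., items with
#' Stage-1 recalibration) keep free, unconstrained intercepts and loadings.
#'
#' @param spec An `rs_model_spec` (not yet identified).
#' @param step `"measurement"` or `"no_response_shift"`.
#' @param except_items Items exempted from the invariance constraints.
#' @param constrain_theta Also constrain residual variances equal across
#'   occasions (enables the nonuniform-recalibration search).
#' @return The identified `rs_model_spec`.
#' @export
identify_model <- function(spec, step = c("measurement", "no_response_shift"),
                           except_items = character(), constrain_theta = FALSE) {
  step <- match.arg(step)
  if (!is.null(spec$identified)) abort("model is already identified; rebuild the spec first")
  if (step == "measurement") {
    for (f in 1:2) {
      spec <- set_param(spec, paste0("kappa_", f), free = FALSE, value = 0)
      spec <- set_param(spec, paste0("phi_", f, "_", f), free = FALSE, value = 1)
    }
  } else {
    spec <- set_param(spec, "kappa_1", free = FALSE, value = 0)
    spec <- set_param(spec, "phi_1_1", free = FALSE, value = 1)
    equal_load <- identical(spec$two_item_strategy, "equal_loadings")
    for (it in setdiff(spec$items, except_items)) {
      spec <- set_param(spec, paste0("tau_", it, "@1"), group = paste0("tau_", it))
      spec <- set_param(spec, paste0("tau_", it, "@2"), group = paste0("tau_", it))
      lg <- if (equal_load) "lambda_eq" else paste0("lambda_", it)
      spec <- set_param(spec, paste0("lambda_", it, "@1"), group = lg)
      spec <- set_param(spec, paste0("lambda_", it, "@2"), group = lg)
      if (constrain_theta &&
          all(paste0("theta_", it, c("@1", "@2")) %in% spec$params$label)) {
        spec <- set_param(spec, paste0("theta_", it, "@1"), group = paste0("theta_", it))
        spec <- set_param(spec, paste0("theta_", it, "@2"), group = paste0("theta_", it))
      }
    }
  }
  spec$identified <- step
  spec$except_items <- except_items
  spec
}

#' Identification strategies for two-item scales
#'
#' A two-indicator-per-occasion factor model is under-identified without an
#' extra restriction. `zero_residual_cov` removes the same-item cross-occasion
#' residual covariances; `equal_loadings` constrains the two items' loadings
#' to be equal within each occasion. `auto` is resolved at fitting time by
#' keeping the strategy with the better (lower) test statistic.
#'
#' @param spec An `rs_model_spec` with exactly two items.
#' @param strategy `"zero_residual_cov"`, `"equal_loadings"`, or `"auto"`.
#' @return The restricted `rs_model_spec` (or, for `"auto"`, the spec tagged
#'   for resolution during fitting).
#' @export
two_item_identification <- function(spec, strategy = c("zero_residual_cov",
                                                       "equal_loadings", "auto")) {
  strategy <- match.arg(strategy)
  if (length(spec$items) != 2L) abort("two_item_identification requires exactly 2 items")
  if (strategy == "auto") {
    spec$two_item_strategy <- "auto"
    return(spec)
  }
  if (strategy == "zero_residual_cov") {
    for (it in spec$items) {
      spec <- set_param(spec, paste0("theta_", it, "@2_", it, "@1"), free = FALSE, value = 0)
    }
  } else {
    for (o in 1:2) {
      for (it in spec$items) {
        spec <- set_param(spec, paste0("lambda_", it, "@", o),
                          group = paste0("lambda_eq_occ", o))
      }
    }
  }
  spec$two_item_strategy <- strategy
  spec
}

#' @export
#' @rdname build_model
#' @param spec An `rs_model_spec`.
model_df <- function(spec) {
  p <- nrow(spec$vars)
  n_mom <- p + p * (p + 1) / 2 - length(spec$derived_vars %||% character(0))
  as.integer(n_mom - n_free_params(spec))
}

#' Adaptation for dichotomous indicators
#'
#' Tetrachoric-based scales fix the underlying SDs at one, so across-occasion
#' variance differences cannot be expressed through the residual variances of
#' a constrained model. The no-response-shift model therefore receives free
#' scale factors for the occasion-2 indicators (occasion 1 fixed at 1; the
#' first dichotomous item's occasion-2 factor is also fixed at 1 for
#' identification when all items are dichotomous). Loadings of dichotomous
#' items are excluded from the response-shift candidate set: only intercept
#' (recalibration) shifts are detectable, judged from overall model fit.
#'
#' @param spec An identified `rs_model_spec`.
#' @param dichotomous_items Items measured with two categories (default: all).
#' @return The adapted `rs_model_spec`.
#' @export
dichotomous_adaptation <- function(spec, dichotomous_items = NULL) {
  if (is.null(dichotomous_items)) {
    dichotomous_items <- if (length(spec$dichotomous_items %||% character(0))) {
      spec$dichotomous_items
    } else {
      spec$items
    }
  }
  all_dich <- setequal(dichotomous_items, spec$items)
  if (!all_dich) {
    warn("mixed binary/polytomous scale: scale factors applied to the dichotomous items only")
  }
  if (identical(spec$identified, "no_response_shift")) {
    anchor <- if (all_dich) dichotomous_items[1] else character(0)
    for (it in setdiff(dichotomous_items, anchor)) {
      spec <- set_param(spec, paste0("scalefac_", it, "@2"), free = TRUE)
    }
  }
  spec$dichotomous <- TRUE
  spec$dichotomous_items <- dichotomous_items
  spec
}

# ---------------------------------------------------------------------------
# Parameter vector <-> matrices
# ---------------------------------------------------------------------------

# free-parameter groups in a stable order
param_groups <- function(spec) {
  pt <- spec$params
  g <- ifelse(is.na(pt$group), pt$label, pt$group)
  unique(g[pt$free])
}

n_free_params <- function(spec) length(param_groups(spec))

# Precompiled filler: returns function(theta) -> list(lambda, tau, theta, phi,
# kappa, scale) and the start vector.
compile_spec <- function(spec) {
  p <- nrow(spec$vars)
  K <- spec$n_factors
  pt <- spec$params
  g <- ifelse(is.na(pt$group), pt$label, pt$group)
  groups <- param_groups(spec)
  dims <- list(lambda = c(p, K), tau = c(p, 1L), theta = c(p, p),
               phi = c(K, K), kappa = c(K, 1L), scale = c(p, 1L))
  base <- lapply(dims, function(d) matrix(0, d[1], d[2]))
  asg <- list()
  for (i in seq_len(nrow(pt))) {
    mat <- pt$matrix[i]
    lin <- pt$row[i] + (pt$col[i] - 1L) * dims[[mat]][1]
    lin2 <- NA_integer_
    if (mat %in% c("theta", "phi") && pt$row[i] != pt$col[i]) {
      lin2 <- pt$col[i] + (pt$row[i] - 1L) * dims[[mat]][1]
    }
    if (pt$free[i]) {
      asg[[length(asg) + 1L]] <- list(mat = mat, lin = lin, lin2 = lin2,
                                      tidx = match(g[i], groups))
    } else {
      base[[mat]][lin] <- pt$value[i]
      if (!is.na(lin2)) base[[mat]][lin2] <- pt$value[i]
    }
  }
  start <- numeric(length(groups))
  for (i in seq_len(nrow(pt))) {
    if (pt$free[i]) start[match(g[i], groups)] <- pt$value[i]
  }
  fill <- function(theta) {
    m <- base
    for (a in asg) {
      m[[a$mat]][a$lin] <- theta[a$tidx]
      if (!is.na(a$lin2)) m[[a$mat]][a$lin2] <- theta[a$tidx]
    }
    m
  }
  list(fill = fill, start = start, groups = groups, asg = asg)
}

#' Model-implied moments
#'
#' Mean vector and covariance matrix implied by a parameter set:
#' `mu = D (tau + Lambda kappa)`, `Sigma = D (Lambda Phi Lambda' + Theta) D`
#' with `D` the diagonal matrix of indicator scale factors (identity unless
#' the dichotomous adaptation is active).
#'
#' @param spec An `rs_model_spec`.
#' @param theta Numeric vector of free parameters (defaults to start values).
#' @return List with `mu` and `sigma`.
#' @export
model_implied_moments <- function(spec, theta = NULL) {
  cs <- compile_spec(spec)
  if (is.null(theta)) theta <- cs$start
  if (length(theta) != length(cs$start)) {
    abort(sprintf("theta has length %d; model has %d free parameters",
                  length(theta), length(cs$start)))
  }
  m <- cs$fill(theta)
  d <- as.vector(m$scale)
  mu <- d * as.vector(m$tau + m$lambda %*% m$kappa)
  sigma <- (m$lambda %*% m$phi %*% t(m$lambda) + m$theta) * tcrossprod(d)
  names(mu) <- spec$vars$var
  dimnames(sigma) <- list(spec$vars$var, spec$vars$var)
  dv <- spec$derived_vars %||% character(0)
  if (length(dv)) {
    # unit tetrachoric variances: residual variances are derived, not fitted
    j <- match(dv, spec$vars$var)
    sigma[cbind(j, j)] <- 1
  }
  list(mu = mu, sigma = sigma)
}

# Release the across-occasion equality constraint of one candidate (a tau or
# lambda group): both occasions become separately free parameters.
release_constraint <- function(spec, group) {
  i <- which(!is.na(spec$params$group) & spec$params$group == group)
  if (!length(i)) abort(sprintf("no equality group named %s", group))
  spec$params$group[i] <- NA_character_
  spec
}
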