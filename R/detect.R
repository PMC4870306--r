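# The four-step detection procedure of both stages: the Stage-1 battery and
# per-item reports, the Stage-2 iterative constraint-release search, shift
# classification, and the decomposition of change.

#' Run the Stage-1 analysis for one set of items
#'
#' Step 1: likelihood-ratio battery of underlying bivariate normality over all
#' variable pairs (Bonferroni-corrected exact tests; the tenability flag uses
#' the RMSEA criterion), with dichotomous variables tested in triplets.
#' Step 2: threshold-invariance test per item (4+ categories). Step 3:
#' individual-threshold follow-up (5+ categories) for items failing Step 2;
#' those items get occasion-specific thresholds and are excluded from Stage-2
#' invariance constraints and change interpretation. Step 4: longitudinal
#' scale fit per item and standardized change (effect size d). Finally the
#' Stage-1 moments are assembled and (optionally) their asymptotic covariance
#' is estimated.
#'
#' @param data Wide data frame: one row per subject, response columns named
#'   `"item@occasion"` (see [read_ordinal_data()]).
#' @param config A [scale_config()].
#' @param scale Subscale to analyze (required when `config` has several).
#' @param alpha Significance level (family-wise for the Step-1 battery).
#' @param rmsea_cutoff Stage-1 approximate-fit cutoff (default 0.1).
#' @param acov Estimate the asymptotic covariance of the moments?
#' @param method Estimation flow for the per-item fits (see
#'   [fit_item_longitudinal()]).
#' @return A `stage1_result`: per-item `report` tibble (thresholds, means, SDs,
#'   rho, invariance tests, effect sizes), the Step-1 `battery`, the
#'   `moments`, item fits, and exclusions.
#' @export
run_stage1 <- function(data, config, scale = NULL, alpha = 0.05,
                       rmsea_cutoff = 0.1, acov = TRUE,
                       method = c("two_step", "ml")) {
  method <- match.arg(method)
  cfg <- config_items(config, scale)
  items <- cfg$item
  n <- length(items)
  vars <- variable_grid(items)
  need <- vars$var
  miss_cols <- setdiff(need, names(data))
  if (length(miss_cols)) {
    abort(paste("missing response columns:", paste(miss_cols, collapse = ", ")))
  }
  X <- as.matrix(data[, need])
  storage.mode(X) <- "integer"
  complete <- stats::complete.cases(X)
  if (any(!complete)) {
    message(sprintf("listwise deletion: %d of %d subjects dropped (missing responses)",
                    sum(!complete), length(complete)))
    X <- X[complete, , drop = FALSE]
  }
  N <- nrow(X)
  if (N < 1L) abort("no complete cases")
  m_of <- setNames(cfg$m, cfg$item)
  for (i in seq_len(nrow(vars))) {
    m <- m_of[[vars$item[i]]]
    bad <- which(X[, i] < 1L | X[, i] > m)
    if (length(bad)) {
      abort(sprintf("response out of range 1..%d for %s (e.g. subject row %d)",
                    m, vars$var[i], bad[1]))
    }
  }

  pair_tab <- function(i, j) {
    table(factor(X[, i], levels = seq_len(m_of[[vars$item[i]]])),
          factor(X[, j], levels = seq_len(m_of[[vars$item[j]]])))
  }

  # --- Step 1: normality battery -------------------------------------------
  alpha_star <- bonferroni_alpha(alpha, n)
  battery <- list()
  pairs <- utils::combn(nrow(vars), 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    m1 <- m_of[[vars$item[i]]]; m2 <- m_of[[vars$item[j]]]
    if (m1 == 2L && m2 == 2L) next  # handled by triplets
    bt <- bvn_test(pair_tab(i, j), rmsea_cutoff = rmsea_cutoff, alpha = alpha_star)
    battery[[length(battery) + 1L]] <- mutate(bt, var1 = vars$var[i], var2 = vars$var[j],
                                              .before = 1)
  }
  battery <- if (length(battery)) bind_rows(battery) else
    tibble(var1 = character(), var2 = character(), df = integer(), lr_stat = double(),
           p = double(), rmsea = double(), applicable = logical(), bvn_ok = logical(),
           reject_exact = logical())
  dich_vars <- which(vapply(vars$item, function(it) m_of[[it]] == 2L, logical(1)))
  triplets <- NULL
  if (length(dich_vars) >= 3L) {
    trc <- utils::combn(dich_vars, 3)
    triplets <- purrr::map_dfr(seq_len(ncol(trc)), function(k) {
      idx <- trc[, k]
      arr <- table(factor(X[, idx[1]], levels = 1:2),
                   factor(X[, idx[2]], levels = 1:2),
                   factor(X[, idx[3]], levels = 1:2))
      mutate(tvn_test(array(arr, c(2, 2, 2)), alpha = alpha_star),
             var1 = vars$var[idx[1]], var2 = vars$var[idx[2]], var3 = vars$var[idx[3]],
             .before = 1)
    })
  }
  bvn_flag <- vapply(vars$var, function(v) {
    rows <- battery[battery$var1 == v | battery$var2 == v, ]
    ok <- all(rows$bvn_ok[rows$applicable], na.rm = TRUE)
    if (!is.null(triplets)) {
      tri <- triplets[triplets$var1 == v | triplets$var2 == v | triplets$var3 == v, ]
      ok <- ok && all(tri$rmsea <= rmsea_cutoff, na.rm = TRUE)
    }
    ok
  }, logical(1))
  item_bvn <- vapply(items, function(it) {
    all(bvn_flag[vars$var[vars$item == it]])
  }, logical(1))
  if (any(!item_bvn)) {
    warn(paste("underlying normality questionable; consider eliminating the offending variable(s):",
               paste(items[!item_bvn], collapse = ", ")))
  }

  # --- Steps 2-3: threshold invariance -------------------------------------
  inv <- purrr::map_dfr(items, function(it) {
    i1 <- which(vars$var == paste0(it, "@1")); i2 <- which(vars$var == paste0(it, "@2"))
    mutate(threshold_invariance_test(pair_tab(i1, i2), alpha = alpha), item = it, .before = 1)
  })
  excluded <- inv$item[inv$decision == "reject"]
  followup <- NULL
  if (length(excluded)) {
    followup <- purrr::map_dfr(excluded, function(it) {
      m <- m_of[[it]]
      if (m < 5L) return(tibble())
      i1 <- which(vars$var == paste0(it, "@1")); i2 <- which(vars$var == paste0(it, "@2"))
      tab <- pair_tab(i1, i2)
      purrr::map_dfr(seq_len(m - 1L), function(ix) {
        mutate(individual_threshold_test(tab, ix, alpha = alpha), item = it, .before = 1)
      })
    })
  }

  # --- Step 4: per-item scales and change ----------------------------------
  fits <- list()
  for (it in items) {
    i1 <- which(vars$var == paste0(it, "@1")); i2 <- which(vars$var == paste0(it, "@2"))
    tab <- pair_tab(i1, i2)
    if (it %in% excluded) {
      # recalibrated item: occasion-specific thresholds straight from the
      # margins (each occasion's underlying variable standard normal), rho
      # given those
      th1 <- margin_qnorm_thresholds(rowSums(tab))
      th2 <- margin_qnorm_thresholds(colSums(tab))
      pf <- polychoric(tab, fixed = list(t1 = th1, t2 = th2))
      sc <- underlying_scale(list(th1, th2), c(0, 0), c(1, 1), "standard")
      fits[[it]] <- structure(list(
        scale = sc, ref_scale = sc, rho = pf$rho, loglik = pf$loglik,
        sat_loglik = pf$sat_loglik, lr_stat = pf$lr_stat, df = pf$df,
        n = sum(tab), m = m_of[[it]], collapse_map = seq_len(m_of[[it]]),
        convergence = 0L, free_thr = TRUE
      ), class = "item_scale_fit")
    } else {
      f <- fit_item_longitudinal(tab = tab, method = method)
      f$free_thr <- FALSE
      fits[[it]] <- f
    }
  }
  scales <- lapply(fits, `[[`, "scale")
  # moments enter Stage 2 in the alternative parameterization (free variance
  # moments; the standard identification makes them deterministically
  # constrained and the weight matrix singular)
  scales_alt <- lapply(scales, reparameterize, target = "alternative")
  rho_within <- lapply(fits, `[[`, "rho")

  # --- cross-variable correlations (scales fixed) --------------------------
  cross <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (vars$item[i] == vars$item[j]) next
    t1 <- std_thresholds(scales[[vars$item[i]]], vars$occasion[i])
    t2 <- std_thresholds(scales[[vars$item[j]]], vars$occasion[j])
    pf <- polychoric(pair_tab(i, j), fixed = list(t1 = t1, t2 = t2))
    cross[[length(cross) + 1L]] <- tibble(var1 = vars$var[i], var2 = vars$var[j], rho = pf$rho)
  }
  cross <- if (length(cross)) {
    bind_rows(cross)
  } else {
    tibble(var1 = character(), var2 = character(), rho = double())
  }
  moments <- assemble_moments(scales_alt, rho_within, cross, N)

  effects <- purrr::map_dfr(items, function(it) {
    if (it %in% excluded) {
      return(tibble(item = it, change = NA_real_, sd_diff = NA_real_, d = NA_real_,
                    magnitude = NA_character_))
    }
    mutate(stage1_effect_size(scales[[it]], rho_within[[it]]), item = it, .before = 1)
  })

  out <- structure(list(
    items = items, vars = vars, m = m_of, n = N, alpha = alpha,
    alpha_star = alpha_star, battery = battery, triplets = triplets,
    invariance = inv, followup = followup, excluded = excluded,
    fits = fits, cross = cross, moments = moments, effects = effects,
    item_bvn = item_bvn, data_matrix = X, method = method,
    acov_ill_conditioned = FALSE
  ), class = "stage1_result")
  if (acov) out <- estimate_acov(out)

  # Wald p for the mean change, from the moment acov when available
  out$effects$p <- NA_real_
  if (!is.null(out$moments$acov)) {
    lab <- moment_labels(vars)
    for (it in setdiff(items, excluded)) {
      a <- match(paste0("mean_", it, "@1"), lab)
      b <- match(paste0("mean_", it, "@2"), lab)
      v <- out$moments$acov[b, b] + out$moments$acov[a, a] - 2 * out$moments$acov[a, b]
      if (is.finite(v) && v > 0) {
        z <- (out$moments$mu[paste0(it, "@2")] - out$moments$mu[paste0(it, "@1")]) / sqrt(v)
        out$effects$p[out$effects$item == it] <- 2 * pnorm(-abs(z))
      }
    }
  }
  out$report <- stage1_report(out)
  out
}

# Per-item summary in the source study's layout: thresholds in the standard
# identification, means/SDs in the alternative identification.
stage1_report <- function(x) {
  purrr::map_dfr(x$items, function(it) {
    f <- x$fits[[it]]
    sc <- f$scale
    alt <- reparameterize(sc, "alternative")
    inv <- x$invariance[x$invariance$item == it, ]
    eff <- x$effects[x$effects$item == it, ]
    tibble(
      item = it, m = x$m[[it]], bvn = x$item_bvn[[it]],
      inv_df = inv$df_diff, inv_chisq = inv$chisq_diff, inv_p = inv$p,
      decision = inv$decision,
      thresholds = list(sc$thresholds),
      mean_pre = if (sc$occasion_specific) NA_real_ else alt$means[1],
      mean_post = if (sc$occasion_specific) NA_real_ else alt$means[2],
      sd_pre = if (sc$occasion_specific) NA_real_ else alt$sds[1],
      sd_post = if (sc$occasion_specific) NA_real_ else alt$sds[2],
      rho = f$rho, d = eff$d, p = eff$p, stars = p_stars(eff$p),
      excluded = it %in% x$excluded
    )
  })
}

#' @export
print.stage1_result <- function(x, ...) {
  cat(sprintf("<stage1_result> %d items, N = %d (alpha* = %.4g for %d normality tests)\n",
              length(x$items), x$n, x$alpha_star, nrow(x$battery) +
                if (is.null(x$triplets)) 0L else nrow(x$triplets)))
  if (length(x$excluded)) {
    cat("  threshold invariance rejected (excluded from Stage-2 constraints):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  print(x$report %>% select(-"thresholds"), n = Inf)
  invisible(x)
}

#' @export
tidy.stage1_result <- function(x, ...) x$report

#' @export
glance.stage1_result <- function(x, ...) {
  tibble(
    n_items = length(x$items), n = x$n,
    bvn_all = all(x$item_bvn), n_excluded = length(x$excluded),
    acov = !is.null(x$moments$acov)
  )
}

# ---------------------------------------------------------------------------
# Stage-2 search
# ---------------------------------------------------------------------------

#' Classify a freed measurement parameter as a response-shift type
#'
#' Intercept differences are uniform recalibration, factor-loading value
#' differences are reprioritization, residual-variance differences are
#' nonuniform recalibration; a change in the zero/nonzero pattern of loadings
#' (a loading significant at one occasion only) is reconceptualization.
#' Structural parameters (factor means/variances) are not response-shift
#' parameters.
#'
#' @param group Parameter (equality-group) label, e.g. `"tau_item3"`.
#' @return Character scalar.
#' @export
classify_shift <- function(group) {
  if (grepl("^tau_", group)) return("uniform_recalibration")
  if (grepl("^lambda_", group)) return("reprioritization")
  if (grepl("^theta_", group)) return("nonuniform_recalibration")
  abort(sprintf("'%s' is not a measurement (response-shift) parameter", group))
}

shift_candidates <- function(spec, include_theta = FALSE) {
  pt <- spec$params
  grp <- unique(pt$group[!is.na(pt$group)])
  cand <- tibble(group = grp) %>%
    filter(grepl("^(tau|lambda|theta)_", .data$group)) %>%
    mutate(
      type = vapply(.data$group, classify_shift, character(1), USE.NAMES = FALSE),
      item = sub("^(tau|lambda|theta)_", "", .data$group),
      priority = dplyr::case_when(
        .data$type == "uniform_recalibration" ~ 1L,
        .data$type == "reprioritization" ~ 2L,
        TRUE ~ 3L
      )
    )
  if (!include_theta) cand <- filter(cand, .data$type != "nonuniform_recalibration")
  if (isTRUE(spec$dichotomous)) {
    cand <- filter(cand, !(.data$type == "reprioritization" &
                             .data$item %in% spec$dichotomous_items))
  }
  # two-item scales: the choice of which intercept to free is statistically
  # arbitrary, so intercepts enter the candidate set only for the explicitly
  # chosen item (free_intercept)
  if (length(spec$items) == 2L) {
    cand <- filter(cand, .data$type != "reprioritization")
    cand <- filter(cand, .data$type != "uniform_recalibration" |
                     .data$item %in% (spec$free_intercept %||% character(0)))
  }
  cand %>% mutate(item_idx = match(.data$item, spec$items)) %>%
    arrange(.data$priority, .data$item_idx)
}

#' Iterative search for response shifts
#'
#' Greedy Step-3 procedure: starting from the fitted no-response-shift model,
#' each still-constrained candidate parameter (intercepts and loadings; also
#' residual variances if constrained and enabled) is freed one at a time, the
#' model is refitted, and the release with the largest 1-df chi-square
#' improvement is kept; iteration stops when the best release is no longer
#' significant at `alpha_stop`. The search only starts if the global
#' no-response-shift vs measurement-model difference test is significant (for
#' all-dichotomous scales: if the overall fit of the no-response-shift model is
#' rejected), mirroring the two-step decision logic of the procedure.
#'
#' @param no_shift_fit `sem_fit` of the no-response-shift model.
#' @param measurement_fit `sem_fit` of the measurement model (used by the
#'   gate; may be `NULL` with `gate = FALSE`).
#' @param alpha_stop Stopping significance level (default 0.05).
#' @param include_theta Also search residual variances (nonuniform
#'   recalibration), if they were constrained.
#' @param bonferroni Divide `alpha_stop` by the number of candidates.
#' @param gate Require the global test before searching.
#' @return List: `findings` tibble (ordered releases with statistics and
#'   classification), `final` fit, `global` gate test, `candidates`.
#' @export
search_shifts <- function(no_shift_fit, measurement_fit = NULL, alpha_stop = 0.05,
                          include_theta = FALSE, bonferroni = FALSE, gate = TRUE) {
  spec <- no_shift_fit$spec
  if (!identical(spec$identified, "no_response_shift")) {
    abort("search starts from a fitted no-response-shift model")
  }
  N <- no_shift_fit$moments$n
  global <- NULL
  proceed <- TRUE
  if (gate) {
    if (isTRUE(spec$dichotomous)) {
      global <- tibble(chisq = no_shift_fit$statistic, df = no_shift_fit$df,
                       p = no_shift_fit$fit$p)
      proceed <- is.finite(global$p) && global$p < alpha_stop
    } else {
      if (is.null(measurement_fit)) abort("gate = TRUE needs the measurement-model fit")
      global <- chisq_diff_test(.diff_stat(no_shift_fit), no_shift_fit$df,
                                .diff_stat(measurement_fit), measurement_fit$df, N)
      proceed <- is.finite(global$p) && global$p < alpha_stop
    }
  }

  cand <- shift_candidates(spec, include_theta)
  alpha_use <- if (bonferroni && nrow(cand)) alpha_stop / nrow(cand) else alpha_stop
  findings <- tibble(
    order = integer(), group = character(), type = character(), item = character(),
    chisq_diff = double(), df_diff = integer(), p = double(), direction = double()
  )
  current <- no_shift_fit
  if (proceed) {
    repeat {
      if (!nrow(cand)) break
      stats <- rep(NA_real_, nrow(cand))
      fits <- vector("list", nrow(cand))
      for (k in seq_len(nrow(cand))) {
        sp <- release_constraint(current$spec, cand$group[k])
        f <- tryCatch(
          suppressWarnings(
            fit_sem(sp, current$moments, estimator = .base_estimator(current$estimator),
                    mean_adjusted = grepl("mean-adjusted", current$estimator))
          ),
          error = function(e) {
            warn(sprintf("candidate %s skipped (refit failed: %s)",
                         cand$group[k], conditionMessage(e)))
            NULL
          }
        )
        if (is.null(f) || !f$converged) next
        fits[[k]] <- f
        stats[k] <- max(.diff_stat(current) - .diff_stat(f), 0)
      }
      if (all(is.na(stats))) break
      best <- which.max(replace(stats, is.na(stats), -Inf))  # candidates pre-sorted: ties
      p_best <- pchisq(stats[best], 1, lower.tail = FALSE)   # go to intercepts/item order
      if (!is.finite(p_best) || p_best >= alpha_use) break
      ff <- fits[[best]]
      td <- tidy(ff)
      mat <- sub("_.*$", "", cand$group[best])
      it <- cand$item[best]
      v1 <- td$estimate[td$label == paste0(mat, "_", it, "@1")]
      v2 <- td$estimate[td$label == paste0(mat, "_", it, "@2")]
      findings <- bind_rows(findings, tibble(
        order = nrow(findings) + 1L, group = cand$group[best],
        type = cand$type[best], item = it,
        chisq_diff = stats[best], df_diff = 1L, p = p_best,
        direction = if (length(v1) == 1L && length(v2) == 1L) v2 - v1 else NA_real_
      ))
      current <- ff
      cand <- cand[-best, ]
    }
  }
  # post-hoc reconceptualization check: loading significant at one occasion only
  td <- tidy(current)
  lam <- td %>% filter(.data$matrix == "lambda", .data$free) %>%
    mutate(signif = abs(.data$statistic) > qnorm(0.975))
  recon <- character(0)
  for (it in spec$items) {
    z <- lam$signif[lam$label %in% paste0("lambda_", it, c("@1", "@2"))]
    if (length(z) == 2L && !all(is.na(z)) && xor(isTRUE(z[1]), isTRUE(z[2]))) {
      recon <- c(recon, it)
    }
  }
  if (length(recon)) {
    findings$type[findings$item %in% recon & findings$type == "reprioritization"] <-
      "reconceptualization"
  }
  list(findings = findings, final = current, global = global, candidates = cand,
       reconceptualization_items = recon)
}

.base_estimator <- function(tag) sub("\\+mean-adjusted$", "", tag)

# statistic used for nested differences: the unadjusted discrepancy under
# DWLS/ULS (mean-adjusted values are not chi-square-differencable), the WLS
# chi-square otherwise
.diff_stat <- function(fit) {
  if (grepl("mean-adjusted", fit$estimator) || fit$estimator == "uls") fit$F_min else fit$statistic
}

# ---------------------------------------------------------------------------
# Step 4: true change and decomposition
# ---------------------------------------------------------------------------

delta_se <- function(fit, fun) {
  if (is.null(fit$vcov)) return(NA_real_)
  th <- fit$theta
  h <- pmax(abs(th), 1) * 1e-6
  g <- vapply(seq_along(th), function(j) {
    tp <- th; tm <- th
    tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
    (fun(tp) - fun(tm)) / (2 * h[j])
  }, numeric(1))
  sqrt(max(as.numeric(g %*% fit$vcov %*% g), 0))
}

#' True change in the common factors
#'
#' Effect size of change in the common-factor means from the final
#' (response-shift-accounted) model:
#' `d = (kappa2 - kappa1) / sqrt(phi11 + phi22 - 2 phi21)`, with a Wald test
#' for the mean difference.
#'
#' @param fit A `sem_fit` identified with `kappa1 = 0` (no-response-shift /
#'   response-shift model).
#' @return One-row tibble: `change`, `sd_diff`, `d`, `se`, `p`, `stars`.
#' @export
true_change <- function(fit) {
  m <- fit$matrices
  change <- m$kappa[2] - m$kappa[1]
  v <- m$phi[1, 1] + m$phi[2, 2] - 2 * m$phi[2, 1]
  if (!is.finite(v) || v <= 0) abort("degenerate factor covariance; d undefined")
  cs <- compile_spec(fit$spec)
  k2 <- match("kappa_2", cs$groups)
  se <- if (!is.na(k2) && !is.null(fit$vcov)) sqrt(fit$vcov[k2, k2]) else NA_real_
  p <- if (is.finite(se) && se > 0) 2 * pnorm(-abs(change / se)) else NA_real_
  tibble(change = change, sd_diff = sqrt(v), d = change / sqrt(v),
         se = se, p = p, stars = p_stars(p))
}

#' Decompose modeled change per item
#'
#' Splits the model-implied change of each underlying variable into uniform
#' recalibration (intercept difference), reprioritization/reconceptualization
#' (loading difference times the occasion-2 factor mean), and true change
#' (occasion-1 loading times the occasion-2 factor mean):
#' `mu2 - mu1 = (tau2 - tau1) + (lambda2 - lambda1) kappa2 + lambda1 kappa2`
#' (an exact identity given the `kappa1 = 0` identification). Each component
#' is also expressed as an effect size using the model-implied standard
#' deviation of change of that variable. Items excluded for Stage-1
#' recalibration are flagged as not interpretable.
#'
#' @param fit A `sem_fit` with `kappa1 = 0`.
#' @return Tibble with one row per item: components, effect sizes and
#'   significance of the modeled change.
#' @export
decompose_change <- function(fit) {
  spec <- fit$spec
  if (!identical(spec$identified, "no_response_shift")) {
    abort("decomposition requires the kappa1 = 0 identification (no-response-shift step)")
  }
  m <- fit$matrices
  d <- as.vector(m$scale)
  vars <- spec$vars
  mu <- fit$mu_hat
  sg <- fit$sigma_hat
  cs <- compile_spec(spec)
  fill <- cs$fill
  purrr::map_dfr(spec$items, function(it) {
    i1 <- which(vars$var == paste0(it, "@1"))
    i2 <- which(vars$var == paste0(it, "@2"))
    f1 <- vars$occasion[i1]; f2 <- vars$occasion[i2]
    tau_eff <- d * as.vector(m$tau)
    lam_eff <- d * m$lambda
    recal <- tau_eff[i2] - tau_eff[i1]
    reprior <- (lam_eff[i2, f2] - lam_eff[i1, f1]) * m$kappa[2]
    true_c <- lam_eff[i1, f1] * m$kappa[2]
    modeled <- unname(mu[i2] - mu[i1])
    v_diff <- sg[i1, i1] + sg[i2, i2] - 2 * sg[i1, i2]
    sd_diff <- if (is.finite(v_diff) && v_diff > 0) sqrt(v_diff) else NA_real_
    mod_fun <- function(th) {
      mm <- fill(th)
      dd <- as.vector(mm$scale)
      muv <- dd * as.vector(mm$tau + mm$lambda %*% mm$kappa)
      muv[i2] - muv[i1]
    }
    se <- delta_se(fit, mod_fun)
    p <- if (is.finite(se) && se > 0) 2 * pnorm(-abs(modeled / se)) else NA_real_
    tibble(
      item = it, modeled = modeled, recalibration = recal,
      reprioritization = reprior, true_change = true_c,
      sd_diff = sd_diff, d_modeled = modeled / sd_diff,
      d_recalibration = recal / sd_diff, d_reprioritization = reprior / sd_diff,
      d_true = true_c / sd_diff, p = p, stars = p_stars(p),
      interpretable = !(it %in% (spec$except_items %||% character(0)))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
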