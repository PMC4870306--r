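# Detection orchestration: classification, decomposition, true change, search.

test_that("shift classification maps matrices to types", {
  expect_equal(classify_shift("tau_item3"), "uniform_recalibration")
  expect_equal(classify_shift("lambda_item3"), "reprioritization")
  expect_equal(classify_shift("theta_item3"), "nonuniform_recalibration")
  expect_error(classify_shift("kappa_2"), "not a measurement")
  expect_error(classify_shift("phi_2_1"), "not a measurement")
})

test_that("decomposition identity holds exactly on random fitted models", {
  set.seed(71)
  for (i in 1:20) {
    spec <- identify_model(build_model(paste0("i", 1:4)), "no_response_shift")
    # free a random tau and lambda so the shift components are nonzero
    spec <- ordshift:::release_constraint(spec, sample(paste0("tau_i", 1:4), 1))
    spec <- ordshift:::release_constraint(spec, sample(paste0("lambda_i", 1:4), 1))
    cs <- ordshift:::compile_spec(spec)
    th <- cs$start + runif(length(cs$start), -0.3, 0.3)
    mm <- model_implied_moments(spec, th)
    ms <- structure(list(vars = spec$vars, mu = mm$mu, sigma = mm$sigma,
                         n = 437, acov = NULL), class = "moment_set")
    fit <- suppressWarnings(fit_sem(spec, ms, estimator = "uls"))
    dec <- decompose_change(fit)
    expect_equal(dec$modeled,
                 dec$recalibration + dec$reprioritization + dec$true_change,
                 tolerance = 1e-12)
    mu <- fit$mu_hat
    expect_equal(dec$modeled, unname(mu[5:8] - mu[1:4]), tolerance = 1e-12)
  }
})

test_that("fully invariant models have zero shift components", {
  spec <- identify_model(build_model(c("a", "b", "c")), "no_response_shift")
  cs <- ordshift:::compile_spec(spec)
  th <- cs$start; th[match("kappa_2", cs$groups)] <- 0.4
  mm <- model_implied_moments(spec, th)
  ms <- structure(list(vars = spec$vars, mu = mm$mu, sigma = mm$sigma,
                       n = 437, acov = NULL), class = "moment_set")
  fit <- fit_sem(spec, ms, estimator = "uls")
  dec <- decompose_change(fit)
  expect_equal(dec$recalibration, rep(0, 3), tolerance = 1e-8)
  expect_equal(dec$reprioritization, rep(0, 3), tolerance = 1e-8)
  expect_equal(dec$true_change, 0.4 * fit$matrices$lambda[1:3, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("true change follows the factor-mean formula", {
  spec <- identify_model(build_model(c("a", "b", "c")), "no_response_shift")
  cs <- ordshift:::compile_spec(spec)
  th <- cs$start
  th[match("kappa_2", cs$groups)] <- 0.5
  th[match("phi_2_2", cs$groups)] <- 1.2
  th[match("phi_2_1", cs$groups)] <- 0.8
  mm <- model_implied_moments(spec, th)
  ms <- structure(list(vars = spec$vars, mu = mm$mu, sigma = mm$sigma,
                       n = 437, acov = NULL), class = "moment_set")
  fit <- fit_sem(spec, ms, estimator = "uls")
  tc <- true_change(fit)
  expect_equal(tc$d, 0.5 / sqrt(1 + 1.2 - 2 * 0.8), tolerance = 1e-6)
  expect_equal(tc$change, 0.5, tolerance = 1e-6)
})

test_that("greedy search finds an injected recalibration and is deterministic", {
  cfg <- inject_shift(sim_config(n_subjects = 2000, seed = 404), "intercept",
                      item = 2, delta = 0.4)
  dat <- simulate_ordinal(cfg)
  res <- suppressWarnings(detect_response_shift(dat, sim_scale_config(cfg)))
  expect_gte(nrow(res$findings), 1L)
  expect_equal(res$findings$group[1], "tau_item_2")
  expect_equal(res$findings$type[1], "uniform_recalibration")
  expect_gt(res$findings$direction[1], 0)
  # each accepted release costs exactly one df
  expect_equal(res$no_shift_fit$df - res$final_fit$df, nrow(res$findings))
  # determinism: identical rerun gives the identical sequence
  res2 <- suppressWarnings(detect_response_shift(dat, sim_scale_config(cfg)))
  expect_identical(res$findings$group, res2$findings$group)
  expect_equal(res$findings$chisq_diff, res2$findings$chisq_diff, tolerance = 1e-8)
})

test_that("ignoring an injected recalibration biases the factor-mean change", {
  # population-level sign check: exact moments from a model whose only change
  # is a positive occasion-2 intercept shift (true kappa2 = 0); the constrained
  # no-response-shift fit absorbs part of the shift into the factor mean
  for (delta in c(0.4, -0.4)) {
    gen <- identify_model(build_model(paste0("i", 1:5)), "no_response_shift")
    gen <- ordshift:::release_constraint(gen, "tau_i1")
    cs <- ordshift:::compile_spec(gen)
    th <- cs$start
    th[match("tau_i1@2", cs$groups)] <- delta
    mm <- model_implied_moments(gen, th)
    ms <- structure(list(vars = gen$vars, mu = mm$mu, sigma = mm$sigma,
                         n = 2000, acov = NULL), class = "moment_set")
    ns <- identify_model(build_model(paste0("i", 1:5)), "no_response_shift")
    fit <- suppressWarnings(fit_sem(ns, ms, estimator = "uls"))
    expect_equal(sign(true_change(fit)$change), sign(delta))
    expect_gt(abs(true_change(fit)$change), 0.02)
  }
})

test_that("two-item scales require an explicit intercept choice", {
  cfg <- inject_shift(sim_config(n_subjects = 1500, n_items = 2, m = 5,
                                 thresholds = seq(-1, 1, length.out = 4), seed = 86),
                      "intercept", item = 1, delta = 0.5)
  dat <- simulate_ordinal(cfg)
  conf_no_choice <- sim_scale_config(cfg)
  expect_warning(
    res <- suppressMessages(detect_response_shift(dat, conf_no_choice)),
    "statistically arbitrary"
  )
  expect_equal(nrow(res$findings), 0L)
  conf_choice <- scale_config(conf_no_choice$items,
                              two_item_strategy = c(sim = "zero_residual_cov"),
                              free_intercept = c(sim = "item_1"))
  res2 <- suppressWarnings(detect_response_shift(dat, conf_choice))
  expect_equal(res2$findings$group, "tau_item_1")
})

test_that("single-item scales stop after Stage 1", {
  cfg <- sim_config(n_subjects = 300, n_items = 1, m = 5,
                    thresholds = seq(-1, 1, length.out = 4), seed = 87)
  dat <- simulate_ordinal(cfg)
  expect_message(res <- detect_response_shift(dat, sim_scale_config(cfg)),
                 "single item")
  expect_s3_class(res, "stage1_result")
  expect_false(is.na(res$report$d[1]))
})

test_that("items failing threshold invariance are excluded from interpretation", {
  cfg <- inject_shift(sim_config(n_subjects = 2500, seed = 88), "threshold",
                      item = 4, delta = -0.45, index = c(1, 2, 3))
  dat <- simulate_ordinal(cfg)
  res <- suppressWarnings(detect_response_shift(dat, sim_scale_config(cfg)))
  s1 <- if (inherits(res, "rs_detect")) res$stage1 else res
  expect_true("item_4" %in% s1$excluded)
  expect_true(is.na(s1$report$d[s1$report$item == "item_4"]))
  if (inherits(res, "rs_detect")) {
    dec <- res$decomposition
    expect_false(dec$interpretable[dec$item == "item_4"])
    # excluded items are not shift candidates
    expect_false(any(res$findings$item == "item_4"))
  }
})

test_that("all-dichotomous scales detect intercept shifts via overall fit", {
  cfg <- inject_shift(sim_config(n_subjects = 2000, n_items = 4, m = 2,
                                 thresholds = 0.2, seed = 91),
                      "intercept", item = 2, delta = 0.5)
  res <- suppressWarnings(detect_response_shift(simulate_ordinal(cfg),
                                                sim_scale_config(cfg)))
  # dichotomous pairs carry no bivariate-normality information: triplets used
  expect_equal(nrow(res$stage1$triplets), choose(8, 3))
  expect_equal(res$measurement_fit$df, 15L)
  expect_equal(res$no_shift_fit$df, 18L)
  # only intercepts are candidates; the injected one is found first
  expect_equal(res$findings$group[1], "tau_item_2")
  expect_true(all(res$findings$type == "uniform_recalibration"))
  expect_gt(res$findings$direction[1], 0)
  # null binary data: gate (overall fit of the no-shift model) keeps quiet
  cfg0 <- sim_config(n_subjects = 2000, n_items = 4, m = 2,
                     thresholds = 0.2, seed = 92)
  res0 <- suppressWarnings(detect_response_shift(simulate_ordinal(cfg0),
                                                 sim_scale_config(cfg0)))
  expect_equal(nrow(res0$findings), 0L)
})
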