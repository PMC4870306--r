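# Moment assembly and the asymptotic covariance of the stacked moments.

make_scales <- function() {
  list(
    a = underlying_scale(c(0, 1, 1.8), c(1.2, 1.5), c(1.3, 1.4), "alternative"),
    b = underlying_scale(c(0, 1), c(0.8, 0.7), c(1.1, 1.0), "alternative")
  )
}

test_that("assembled moments have the right structure", {
  ms <- assemble_moments(make_scales(), list(a = 0.6, b = 0.5),
                         tibble::tibble(
                           var1 = c("a@1", "a@1", "a@2", "a@2"),
                           var2 = c("b@1", "b@2", "b@1", "b@2"),
                           rho = c(0.3, 0.25, 0.2, 0.35)
                         ), 437)
  expect_equal(ms$vars$var, c("a@1", "b@1", "a@2", "b@2"))
  expect_equal(unname(diag(ms$sigma)), c(1.3, 1.1, 1.4, 1.0)^2)
  expect_equal(ms$sigma["a@1", "a@2"], 0.6 * 1.3 * 1.4)
  expect_equal(ms$sigma["a@2", "b@1"], 0.2 * 1.4 * 1.1)
  expect_true(isSymmetric(ms$sigma))
})

test_that("zero cross-correlations give a block-diagonal covariance", {
  ms <- assemble_moments(make_scales(), list(a = 0.6, b = 0.5),
                         tibble::tibble(
                           var1 = c("a@1", "a@1", "a@2", "a@2"),
                           var2 = c("b@1", "b@2", "b@1", "b@2"),
                           rho = 0
                         ), 100)
  expect_equal(ms$sigma["a@1", "b@1"], 0)
  expect_equal(ms$sigma["a@2", "b@2"], 0)
  expect_true(ms$sigma["a@1", "a@2"] != 0)
})

test_that("missing pair estimates are reported by name", {
  expect_error(
    assemble_moments(make_scales(), list(a = 0.6, b = 0.5),
                     tibble::tibble(var1 = "a@1", var2 = "b@1", rho = NA_real_), 100),
    "a@1 x b@1"
  )
})

test_that("assembled moments approach the generator's implied moments", {
  cfg <- sim_config(n_subjects = 6000, n_items = 3, m = 5,
                    thresholds = seq(-1.2, 1.2, length.out = 4), seed = 77)
  dat <- simulate_ordinal(cfg)
  s1 <- run_stage1(dat, sim_scale_config(cfg), acov = FALSE)
  imp <- ordshift:::sim_implied_moments(cfg)
  # generator y* is standard-normal-ish; compare correlation structure, which
  # is parameterization-free
  R_hat <- stats::cov2cor(s1$moments$sigma)
  R_true <- stats::cov2cor(imp$sigma)
  expect_lt(max(abs(R_hat - R_true)), 0.05)
})

test_that("acov scales as 1/N and has small cross-item blocks under independence", {
  # independent items: loadings 0, so cross-item correlations are zero
  diags <- sapply(c(400, 1600), function(N) {
    cfg <- sim_config(n_subjects = N, n_items = 2, m = 4, loadings = 0,
                      theta_diag = 1, thresholds = c(-0.8, 0, 0.8), seed = 123)
    s1 <- run_stage1(simulate_ordinal(cfg), sim_scale_config(cfg), acov = TRUE)
    acov <- s1$moments$acov
    lab <- rownames(acov)
    cross <- acov[grepl("mean_item_1", lab), grepl("mean_item_2", lab)]
    c(mean(diag(acov)), max(abs(cross)), max(abs(diag(acov))))
  })
  # quadrupling N divides the variances by ~4
  expect_equal(diags[1, 1] / diags[1, 2], 4, tolerance = 0.35)
  # cross-item mean blocks are tiny relative to the variances
  expect_lt(diags[2, 2], 0.1 * diags[3, 2])
})

test_that("sandwich acov agrees with a bootstrap oracle", {
  set.seed(321)
  cfg <- sim_config(n_subjects = 700, n_items = 2, m = 4,
                    thresholds = c(-0.9, 0.1, 1.0), seed = 55)
  dat <- simulate_ordinal(cfg)
  conf <- sim_scale_config(cfg)
  s1 <- run_stage1(dat, conf, acov = TRUE)
  sel <- c("mean_item_1@1", "mean_item_1@2", "cov_item_1@1_item_1@1",
           "cov_item_1@2_item_1@1", "cov_item_2@1_item_1@1")
  boot <- replicate(150, {
    idx <- sample(nrow(dat), replace = TRUE)
    s1b <- suppressWarnings(suppressMessages(
      run_stage1(dat[idx, ], conf, acov = FALSE)
    ))
    ordshift:::moment_vector(s1b$moments$mu, s1b$moments$sigma)
  })
  rownames(boot) <- rownames(s1$moments$acov)
  vb <- apply(boot[sel, ], 1, var)
  vd <- diag(s1$moments$acov)[sel]
  # variances agree within bootstrap Monte-Carlo error
  expect_equal(unname(vd / vb), rep(1, length(sel)), tolerance = 0.45)
  # a key off-diagonal entry too
  cb <- cov(boot[sel[1], ], boot[sel[2], ])
  expect_lt(abs(s1$moments$acov[sel[1], sel[2]] - cb), 0.5 * abs(cb) + 2e-5)
})
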