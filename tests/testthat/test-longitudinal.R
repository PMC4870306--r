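# Per-item longitudinal scale fits and threshold-invariance tests.

test_that("identical margins give the symmetric solution", {
  m <- c(50, 120, 160, 80, 27)
  fit <- fit_item_longitudinal(margins = list(m, m))
  expect_equal(fit$scale$means, c(0, 0), tolerance = 1e-6)
  expect_equal(fit$scale$sds, c(1, 1), tolerance = 1e-6)
  # joint-ML flow agrees in this symmetric case
  fit2 <- fit_item_longitudinal(margins = list(m, m), method = "ml")
  expect_equal(fit2$scale$means, c(0, 0), tolerance = 1e-4)
})

test_that("published item rows reproduce from printed margins", {
  # 6-category, 5-category and dichotomous items; thresholds printed in the
  # standard identification, means/SDs in the alternative one
  ref <- sf36_stage1_estimates()
  for (it in c("24", "1", "27", "13")) {
    row <- ref[ref$item == it, ]
    fit <- fit_item_longitudinal(margins = list(sf36_margins(it, 1), sf36_margins(it, 2)))
    thr <- fit$scale$thresholds
    printed_thr <- as.numeric(row[paste0("t", seq_along(thr))])
    expect_equal(thr, printed_thr, tolerance = 0.05, ignore_attr = TRUE)
    alt <- reparameterize(fit$scale, "alternative")
    expect_equal(alt$means, c(row$mean_pre, row$mean_post), tolerance = 0.05,
                 ignore_attr = TRUE)
  }
})

test_that("a known mean shift on y* is recovered", {
  set.seed(21)
  delta <- c(-1.2, -0.4, 0.3, 1.1)
  t2std <- (delta - 0.3) / 1  # occasion 2 shifted up by 0.3
  tab <- bvn_table_sampled(delta, t2std, 0.55, 5000)
  fit <- fit_item_longitudinal(tab = tab)
  expect_equal(fit$scale$means[2] - fit$scale$means[1], 0.3, tolerance = 0.06)
  expect_equal(fit$rho, 0.55, tolerance = 0.05)
  fit_ml <- fit_item_longitudinal(tab = tab, method = "ml")
  expect_equal(fit_ml$scale$means[2] - fit_ml$scale$means[1], 0.3, tolerance = 0.06)
})

test_that("dichotomous items fix both SDs at one", {
  tab <- matrix(c(220, 60, 40, 117), 2)
  fit <- fit_item_longitudinal(tab = tab)
  expect_equal(fit$scale$sds, c(1, 1))
  alt <- reparameterize(fit$scale, "alternative")
  # alternative means are -qnorm of the category-1 proportions
  expect_equal(alt$means, -qnorm(c(rowSums(tab)[1] / sum(tab), colSums(tab)[1] / sum(tab))),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("empty categories at both occasions are collapsed with a warning", {
  tab <- matrix(0, 4, 4)
  tab[cbind(c(1, 1, 2, 2, 4, 4), c(1, 2, 2, 4, 4, 1))] <- c(30, 20, 25, 15, 40, 10)
  # category 3 empty in both margins
  expect_warning(fit <- fit_item_longitudinal(tab = tab), "collapsed")
  expect_equal(fit$m, 3L)
  expect_equal(fit$collapse_map, c(1L, 2L, 2L, 4L))
})

test_that("threshold invariance df pattern matches the category count", {
  set.seed(31)
  t6 <- seq(-1.5, 1.5, length.out = 5)
  inv6 <- threshold_invariance_test(bvn_table_sampled(t6, t6, 0.5, 600))
  expect_equal(inv6$df_diff, 3L)
  t5 <- seq(-1.2, 1.2, length.out = 4)
  inv5 <- threshold_invariance_test(bvn_table_sampled(t5, t5, 0.5, 600))
  expect_equal(inv5$df_diff, 2L)
  inv3 <- threshold_invariance_test(bvn_table_sampled(c(-0.5, 0.5), c(-0.5, 0.5), 0.5, 600))
  expect_equal(inv3$decision, "not_applicable")
  inv2 <- threshold_invariance_test(matrix(c(100, 30, 20, 80), 2))
  expect_equal(inv2$decision, "not_applicable")
})

test_that("invariance LR is calibrated under equal thresholds", {
  set.seed(41)
  t6 <- c(-1.3, -0.6, 0.1, 0.8, 1.5)
  stats <- replicate(60, {
    threshold_invariance_test(bvn_table_sampled(t6, t6, 0.6, 500))$chisq_diff
  })
  # mean of a chi-square(3) is 3; allow Monte-Carlo slack
  expect_equal(mean(stats), 3, tolerance = 0.35)
})

test_that("individual threshold tests localize a shifted threshold", {
  set.seed(51)
  d <- c(-1.4, -0.7, 0, 0.7, 1.4)
  d2 <- d; d2[1] <- d2[1] + 0.5
  tab <- bvn_table_sampled(d, d2, 0.5, 3000)
  stats <- vapply(1:5, function(ix) individual_threshold_test(tab, ix)$chisq_diff,
                  numeric(1))
  expect_equal(which.max(stats), 1L)
  expect_equal(individual_threshold_test(tab, 1)$df_diff, 1L)
  # four categories: cannot attribute non-invariance
  tab4 <- bvn_table_sampled(d[1:3], d[1:3], 0.5, 500)
  expect_equal(individual_threshold_test(tab4, 1)$decision, "not_applicable")
})
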