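test_that("metric z-scoring uses the sample SD and respects missing values", {
  z <- zscore_metric(c(0, 2, 1))
  expect_equal(z, c(-1, 1, 0))
  expect_equal(zscore_metric(c(0, 2, 4))[1], -1)          # sd = 2
  zz <- zscore_metric(c(-1.2, 0.3, 0.9, NA, 0))
  expect_true(is.na(zz[4]))
  # idempotence and affine invariance
  set.seed(1); x <- rnorm(10)
  z1 <- zscore_metric(x)
  expect_equal(zscore_metric(z1), z1, tolerance = 1e-12)
  expect_equal(zscore_metric(3.2 * x + 7), z1, tolerance = 1e-12)
  expect_error(zscore_metric(rep(4, 5)), "variance")
  expect_error(zscore_metric(c(1, 2)), "3 non-missing")
})

test_that("composite scores orient metrics and center the cohort", {
  zt <- data.frame(mouse_id = c("a", "b", "c", "d"),
                   m1 = c(1, -1, 0.5, -0.5), m2 = c(-1, 1, -0.5, 0.5))
  s1 <- composite_score(zt, "m1", c(m1 = -1))
  expect_equal(s1$score, -zt$m1)
  s2 <- composite_score(zt, c("m1", "m2"), c(m1 = 1, m2 = 1))
  expect_equal(s2$score, rep(0, 4))
  expect_error(composite_score(zt, c("m1", "m3"), c(m1 = 1, m3 = 1)), "absent")
  expect_error(composite_score(zt, c("m1", "m2"), c(m1 = 1)), "sign-map")
  # fewer than half the metrics present -> missing score
  zt$m2[1] <- NA; zt$m1[1] <- NA
  expect_true(is.na(composite_score(zt, c("m1", "m2"),
                                    c(m1 = 1, m2 = 1))$score[1]))
})

test_that("composite score definitions match the task metric sets", {
  expect_identical(names(mwm_learning_signs),
                   c("latency_slope_d1_2", "latency_slope_d1_3",
                     "latency_day3", "overnight_change_d1_2"))
  expect_true(all(mwm_learning_signs == -1))
  expect_identical(names(mwm_precision_signs),
                   c("quadrant_time_p1", "quadrant_time_p2",
                     "target_crossings_p1", "distance_auc_p1", "distance_auc_p2"))
  expect_identical(unname(mwm_precision_signs), c(1, 1, 1, -1, -1))
  expect_identical(names(apa_learning_signs),
                   c("latency_first_entrance_d2", "path_length_d2",
                     "opposite_quadrant_time_d2"))
  expect_identical(names(apa_precision_signs),
                   c("entrances_d2", "bout_distance_d2", "bout_distance_d3"))
  expect_identical(unname(apa_precision_signs), c(-1, 1, 1))
})

test_that("redundancy filter drops metrics with pairwise R2 >= 0.5", {
  set.seed(2)
  n <- 50
  a <- rnorm(n); b <- rnorm(n)
  tbl <- data.frame(mouse_id = seq_len(n), a = a, dup = a, b = b,
                    lin = 2 * a - 3)
  expect_identical(redundancy_filter(tbl), c("a", "b"))
  tbl2 <- data.frame(a = a, b = b)
  expect_identical(redundancy_filter(tbl2), c("a", "b"))
  expect_error(redundancy_filter(data.frame(a = a)), "2 metrics")
})

test_that("correlation method is chosen by Shapiro-Wilk normality", {
  set.seed(3)
  x <- rnorm(16)
  r1 <- correlate(x, 2 * x)
  expect_identical(r1$method, "PEARSON")
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-6)
  r2 <- correlate(x, exp(10 * x))
  expect_identical(r2$method, "SPEARMAN")
  expect_equal(r2$r, 1)
  expect_error(correlate(x, rep(1, 16)), "constant")
  expect_error(correlate(x[1:3], x[1:3]), "4 paired")
})

test_that("correlation p values are calibrated under the null", {
  set.seed(4)
  p <- replicate(1000, correlate(rnorm(16), rnorm(16))$p)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("Holm-Sidak adjustment matches the closed-form step-down rule", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(rep(0.02, 5)), rep(1 - 0.98^5, 5))
  expect_error(holm_sidak(c(0.1, 0)), "\\(0, 1\\]")
  set.seed(5)
  for (rep in 1:1000) {
    p <- runif(sample(1:10, 1))
    adj <- holm_sidak(p)
    expect_equal(adj, oracle_holm_sidak(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("binomial enrichment equals direct pmf summation", {
  expect_equal(binomial_enrichment(10, 10, 0.5), 0.0009765625)
  expect_equal(binomial_enrichment(0, 50), 1)
  expect_equal(binomial_enrichment(9, 88, 0.05), oracle_binom_tail(9, 88, 0.05),
               tolerance = 1e-12)
  set.seed(6)
  for (rep in 1:200) {
    n <- sample(1:100, 1); k <- sample(0:n, 1); a <- runif(1, 0.01, 0.5)
    expect_equal(binomial_enrichment(k, n, a), oracle_binom_tail(k, n, a),
                 tolerance = 1e-12)
  }
  expect_error(binomial_enrichment(5, 3), "k <= n")
})

test_that("linear predictors are fit by OLS and recover planted slopes", {
  set.seed(7)
  z <- rnorm(16)
  m <- fit_linear_predictor(z, 0.8 * z)
  expect_equal(m$slope, 0.8, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  slopes <- replicate(200, {
    zz <- rnorm(16)
    fit_linear_predictor(zz, 0.7 * zz + rnorm(16, 0, 0.5))$slope
  })
  expect_lt(abs(mean(slopes) - 0.7), 0.05)
  expect_error(fit_linear_predictor(rep(1, 8), rnorm(8)), "degenerate")
})

test_that("cross-cohort evaluation returns R2, F and calibrated p", {
  set.seed(8)
  m <- structure(list(slope = 0.8, intercept = 0.1), class = "linear_predictor")
  z <- rnorm(12)
  # a zero-noise target makes lm warn about a perfect fit; that is the point
  noiseless <- suppressWarnings(predict_and_evaluate(m, z, 0.8 * z + 0.1))
  expect_equal(noiseless$r2, 1, tolerance = 1e-12)
  p_null <- replicate(1000, {
    suppressWarnings(predict_and_evaluate(m, rnorm(12), rnorm(12))$p)
  })
  frac <- mean(p_null < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("planted cross-cohort effects are recovered on average", {
  set.seed(9)
  r2s <- replicate(100, {
    z <- rnorm(11)
    actual <- sqrt(0.5) * z + sqrt(0.5) * rnorm(11)
    m <- structure(list(slope = 0.7, intercept = 0), class = "linear_predictor")
    predict_and_evaluate(m, z, actual)$r2
  })
  expect_lt(abs(mean(r2s) - 0.5), 0.15)
})

test_that("leave-one-out robustness flags single-point artifacts", {
  set.seed(10)
  x <- seq(-2, 2, length.out = 10)
  lin <- loo_robustness(x, 1.5 * x)
  expect_true(lin$robust)
  expect_true(all(lin$p_values < 1e-4))

  # 9 uncorrelated points plus one extreme point manufacturing significance
  set.seed(5)
  x9 <- rnorm(9); y9 <- rnorm(9)
  xa <- c(x9, 3); ya <- c(y9, 3)
  expect_lt(correlate(xa, ya)$p, 0.05)
  expect_gt(correlate(x9, y9)$p, 0.05)      # nothing there without the outlier
  adv <- loo_robustness(xa, ya)
  expect_false(adv$robust)

  n5 <- loo_robustness(1:5 + rnorm(5, 0, 0.1), 1:5)
  expect_length(n5$p_values, 5)
  expect_error(loo_robustness(1:4, 1:4), "5 paired")
})
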