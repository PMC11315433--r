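test_that("mean difference follows the approximation-minus-manual convention", {
  expect_equal(mean_difference(c(1, 2, 3), c(1, 2, 3)), list(mean = 0, sd = 0))

  md <- mean_difference(c(10, 20, 30), c(12, 19, 32))
  expect_equal(md$mean, -1.0)
  expect_equal(md$sd, sqrt(3))

  # antisymmetric mean, symmetric SD
  rev <- mean_difference(c(12, 19, 32), c(10, 20, 30))
  expect_equal(rev$mean, 1.0)
  expect_equal(rev$sd, md$sd)

  expect_error(mean_difference(1:3, 1:4), "pairing error")
  expect_true(is.na(mean_difference(5, 4)$sd))
})

test_that("percent error modes behave as defined", {
  m <- c(100, 200, 400)
  expect_equal(percent_error(m, m, "of_means"), 0)
  expect_equal(percent_error(m, m, "mean_of_ratios"), 0)

  a <- c(110, 190, 460)
  expect_equal(percent_error(a, m, "of_means"), 100 * (760 - 700) / 700)
  expect_equal(percent_error(a, m, "mean_of_ratios"), mean(c(10, -5, 15)))
  expect_equal(percent_error(a, m, "mean_abs_ratio"), mean(c(10, 5, 15)))

  # invariant under a common positive rescaling
  expect_equal(percent_error(3 * a, 3 * m, "of_means"),
               percent_error(a, m, "of_means"))

  expect_error(percent_error(a, c(100, -5, 400)), "must be positive")
})

test_that("pearson_r matches hand computation and bands classify correctly", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)

  expect_error(pearson_r(c(1, 2), c(3, 4)), "length >= 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")

  expect_equal(correlation_strength(c(0.39, -0.39)), c("weak", "weak"))
  expect_equal(correlation_strength(c(0.4, 0.541, 0.699)), rep("moderate", 3))
  expect_equal(correlation_strength(c(0.7, -0.95, 1)), rep("strong", 3))
  expect_error(correlation_strength(1.2), "must lie in")
})

test_that("paired t-test handles regular and degenerate differences", {
  x <- c(5, 6, 7)
  res <- paired_t_test(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  shifted <- paired_t_test(x + 1, x)
  expect_equal(shifted$t, Inf)
  expect_equal(shifted$p, 0)
  expect_equal(paired_t_test(x - 2, x)$t, -Inf)

  # d = (-2, 1, -2): t = -1, two-sided p from t(2)
  res <- paired_t_test(c(10, 21, 30), c(12, 20, 32))
  expect_equal(res$t, -1.0)
  expect_equal(res$p, 2 * pt(-1, df = 2))
  expect_equal(round(res$p, 4), 0.4226)
  expect_equal(res$df, 2)
  # CI against the closed form
  se <- sqrt(3) / sqrt(3)
  expect_equal(res$ci_lower, -1 - qt(0.975, 2) * se)
  expect_equal(res$ci_upper, -1 + qt(0.975, 2) * se)

  expect_error(paired_t_test(1, 2), "at least 2 pairs")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("all statistics agree with brute-force oracles on random vectors", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    a <- runif(n, 50, 400)
    m <- runif(n, 50, 400)

    md <- mean_difference(a, m)
    expect_equal(md$mean, oracle_mean(a - m), tolerance = 1e-10)
    expect_equal(md$sd, oracle_sd(a - m), tolerance = 1e-10)

    expect_equal(percent_error(a, m, "of_means"),
                 100 * (oracle_mean(a) - oracle_mean(m)) / oracle_mean(m),
                 tolerance = 1e-10)

    expect_equal(pearson_r(a, m), oracle_pearson(a, m), tolerance = 1e-10)

    tt <- paired_t_test(a, m)
    ot <- oracle_paired_t(a, m)
    expect_equal(tt$t, ot$t, tolerance = 1e-10)
    expect_equal(tt$p, ot$p, tolerance = 1e-10)
    expect_true(tt$p >= 0 && tt$p <= 1)
    expect_equal(sign(tt$t), sign(md$mean))
  }
})

test_that("evaluate_level assembles one fully hand-checkable row per approximation", {
  co <- toy_cohort() # ap (12,11,13), ipd (24,26,22), measured (250,240,230)
  ap <- approximate_cohort(co)
  ev <- evaluate_level(co, ap, "C2-3")
  expect_equal(ev$approximation, c("ellipse", "triangle", "rectangle"))
  expect_equal(ev$n, rep(3L, 3))

  rect <- c(12 * 24, 11 * 26, 13 * 22)
  m <- c(250, 240, 230)
  row <- ev[ev$approximation == "rectangle", ]
  expect_equal(row$mean_mm2, oracle_mean(rect))
  expect_equal(row$mean_diff_mm2, oracle_mean(rect - m))
  expect_equal(row$sd_diff_mm2, oracle_sd(rect - m))
  expect_equal(row$percent_error, 100 * (oracle_mean(rect) - oracle_mean(m)) / oracle_mean(m))
  expect_equal(row$pearson_r, oracle_pearson(rect, m))
  expect_equal(row$t_statistic, oracle_paired_t(rect, m)$t)

  # the three shape rows share one correlation
  expect_equal(length(unique(round(ev$pearson_r, 12))), 1L)

  expect_error(evaluate_level(co, ap, "C6-7"), "no records at level")
  expect_error(evaluate_level(co, ap, "T1-2"), "unknown level")
})

test_that("a cohort measured exactly as its ellipse evaluates as a perfect model", {
  co <- random_cohort(n = 30, seed = 77)
  co$measured_area_mm2 <- ellipse_area(co$ap_diameter_mm, co$ipd_mm)
  co <- as_cohort(co)
  ev <- evaluate_cohort(co)
  ell <- ev[ev$approximation == "ellipse", ]
  expect_equal(ell$mean_diff_mm2, rep(0, nrow(ell)))
  expect_equal(ell$percent_error, rep(0, nrow(ell)))
  expect_equal(ell$pearson_r, rep(1, nrow(ell)))
  expect_equal(ell$p_value, rep(1, nrow(ell)))
})
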