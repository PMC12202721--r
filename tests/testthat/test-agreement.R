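rand_pairs <- function() {
  x <- rnorm(10, 7, 2.5)
  y <- 0.8 * x + rnorm(10, 1, 1.5)
  list(x = x, y = y)
}

test_that("Lin's CCC matches its closed form and the brute-force oracle", {
  x <- c(-5, 5, -5, 5, -5, 5)      # population variance exactly 25
  expect_equal(lin_ccc(x, x + 10)$estimate, 1 / 3, tolerance = 1e-12)
  expect_equal(lin_ccc(1:8, 1:8)$estimate, 1)
  set.seed(81)
  for (rep in 1:20) {
    p <- rand_pairs()
    expect_equal(lin_ccc(p$x, p$y)$estimate, oracle_ccc(p$x, p$y),
                 tolerance = 1e-12)
    # sample-moment variant differs only in the mean-shift weighting
    s <- lin_ccc(p$x, p$y, normalization = "sample")$estimate
    n <- 10
    expect_equal(s, 2 * cov(p$x, p$y) /
                   (var(p$x) + var(p$y) +
                      (mean(p$x) - mean(p$y))^2),
                 tolerance = 1e-12)
  }
  expect_error(lin_ccc(rep(1, 5), 1:5), "constant")
})

test_that("Pearson r detects exact linear and anti-linear relations and
           matches the covariance formula", {
  x <- c(2, 4, 7, 9, 13)
  expect_equal(pearson_r(x, 3 * x - 2)$estimate, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$estimate, -1, tolerance = 1e-12)
  set.seed(82)
  for (rep in 1:20) {
    p <- rand_pairs()
    expect_equal(pearson_r(p$x, p$y)$estimate, oracle_pearson(p$x, p$y),
                 tolerance = 1e-12)
  }
})

test_that("ICC(3,1) equals the two-way ANOVA closed form, is 1 for
           duplicated or offset columns", {
  x <- c(3, 5, 8, 9, 12, 4)
  expect_equal(icc_3_1(x, x)$estimate, 1)
  expect_equal(icc_3_1(x, x + 2.5)$estimate, 1, tolerance = 1e-12)
  set.seed(83)
  for (rep in 1:20) {
    p <- rand_pairs()
    expect_equal(icc_3_1(p$x, p$y)$estimate, oracle_icc31(p$x, p$y),
                 tolerance = 1e-12)
  }
})

test_that("Fisher z intervals contain the estimate, shrink with n, and
           match the closed form", {
  ci <- fisher_z_ci(0, 103)
  expect_equal(ci$upper, tanh(qnorm(0.975) / 10), tolerance = 1e-12)
  expect_equal(ci$lower, -ci$upper, tolerance = 1e-12)
  expect_equal(unlist(fisher_z_ci(0.9, 10)[c("lower", "upper")]),
               unname(oracle_fisher_ci(0.9, 10)), tolerance = 1e-12,
               ignore_attr = TRUE)
  widths <- vapply(c(5, 10, 30, 100, 500), function(n) {
    ci <- fisher_z_ci(0.6, n); ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  set.seed(84)
  for (r in runif(20, -0.95, 0.95)) {
    ci <- fisher_z_ci(r, 12)
    expect_true(ci$lower <= r && r <= ci$upper)
  }
  d <- fisher_z_ci(1, 10)
  expect_true(d$degenerate)
  expect_equal(c(d$lower, d$upper), c(1, 1))
})

test_that("Bland-Altman reports bias and limits of agreement", {
  x <- c(6.2, 7.9, 5.5, 8.8, 7.1)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  ba <- bland_altman(x, x - 0.2)
  expect_equal(ba$bias, 0.2, tolerance = 1e-12)
  set.seed(85)
  p <- rand_pairs()
  got <- bland_altman(p$x, p$y)
  d <- p$x - p$y
  expect_equal(got$bias, mean(d), tolerance = 1e-12)
  expect_equal(got$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(got$means, (p$x + p$y) / 2)
})

test_that("CV is 100*sd/|mean|, zero for constants, scale-invariant", {
  expect_equal(cv_percent(rep(4.2, 6)), 0)
  expect_equal(cv_percent(c(8, 12)), 100 * sd(c(8, 12)) / 10,
               tolerance = 1e-12)
  set.seed(86)
  v <- rnorm(15, 10, 3)
  expect_equal(cv_percent(3.7 * v), cv_percent(v), tolerance = 1e-12)
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("paired t and one-way ANOVA match textbook formulas", {
  set.seed(87)
  p <- rand_pairs()
  got <- paired_t(p$x, p$y)
  o <- oracle_paired_t(p$x, p$y)
  expect_equal(got$t, o$t, tolerance = 1e-12)
  expect_equal(got$p, o$p, tolerance = 1e-12)
  # forced separation
  y <- rnorm(8)
  expect_lt(paired_t(y + 100, y + rnorm(8, sd = 1e-3))$p, 1e-10)

  groups <- list(rnorm(8, 5), rnorm(10, 6), rnorm(7, 5.5))
  ga <- oneway_anova(groups)
  oa <- oracle_anova(groups)
  expect_equal(ga$F, oa$F, tolerance = 1e-12)
  expect_equal(ga$p, oa$p, tolerance = 1e-12)
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(oneway_anova(same)$F, 0)
  expect_equal(oneway_anova(same)$p, 1)
})

test_that("Lin's inequality |CCC| <= |r| holds and both reach 1 on
           duplicated readings", {
  set.seed(88)
  for (rep in 1:50) {
    p <- rand_pairs()
    expect_lte(abs(lin_ccc(p$x, p$y)$estimate),
               abs(pearson_r(p$x, p$y)$estimate) + 1e-14)
  }
  z <- rnorm(10)
  expect_equal(lin_ccc(z, z)$estimate, 1)
  expect_equal(pearson_r(z, z)$estimate, 1)
  expect_equal(icc_3_1(z, z)$estimate, 1)
})

test_that("coefficients classify into the published qualitative bands", {
  expect_equal(classify_coefficient("ccc", 0.97), "substantial")
  expect_equal(classify_coefficient("ccc", 0.92), "moderate")
  expect_equal(classify_coefficient("ccc", 0.995), "almost perfect")
  expect_equal(classify_coefficient("ccc", 0.5), "poor")
  expect_equal(classify_coefficient("icc", 0.95), "excellent")
  expect_equal(classify_coefficient("icc", 0.25), "poor")
  expect_equal(classify_coefficient("icc", 0.8), "good")
  expect_equal(classify_coefficient("pearson", -0.13), "poor")
  expect_equal(classify_coefficient("pearson", 0.78), "moderate strong")
  expect_equal(classify_coefficient("pearson", 0.85), "very strong")
  expect_equal(classify_coefficient("pearson", 0.05), "none")
  # boundaries resolve upward
  expect_equal(classify_coefficient("ccc", 0.90), "moderate")
  expect_equal(classify_coefficient("icc", 0.9), "excellent")
  expect_error(classify_coefficient("ccc", 1.2), "\\[-1, 1\\]")
})

test_that("the agreement report assembles all statistics coherently", {
  set.seed(89)
  x <- rnorm(10, 7, 2.5)
  y <- x + rnorm(10, 0.1, 0.8)
  rep <- agreement_report(x, y, comparison = "inter-reader TLCO")
  expect_equal(rep$ccc$estimate, oracle_ccc(x, y), tolerance = 1e-12)
  expect_equal(rep$pearson$estimate, cor(x, y), tolerance = 1e-12)
  expect_lte(abs(rep$ccc$estimate), abs(rep$pearson$estimate) + 1e-14)
  expect_equal(rep$cv, cv_percent(c(x, y)))
  expect_equal(rep$bland_altman$bias, mean(x - y))
  expect_true(rep$ccc$ci$lower <= rep$ccc$estimate &&
                rep$ccc$estimate <= rep$ccc$ci$upper)
  expect_output(print(rep), "rho")
  df <- as.data.frame(rep)
  expect_equal(df$ccc, rep$ccc$estimate)
  expect_true(df$ccc_class %in% c("poor", "moderate", "substantial",
                                  "almost perfect"))
})
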