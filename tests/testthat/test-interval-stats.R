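test_that("Wilson interval matches closed forms and the score-test inversion", {
  ci <- wilson_ci(0, 10)
  z <- qnorm(0.975)
  expect_equal(ci$lo, 0)
  expect_equal(ci$hi, z^2 / (10 + z^2), tolerance = 1e-12)
  # independent route: prop.test without continuity correction inverts the
  # same score test
  set.seed(3)
  for (rep in 1:30) {
    n <- sample(5:200, 1); k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    ref <- suppressWarnings(prop.test(k, n, correct = FALSE))$conf.int
    expect_equal(c(ci$lo, ci$hi), as.numeric(ref), tolerance = 1e-10)
    expect_gte(ci$lo, 0); expect_lte(ci$hi, 1)
    expect_lte(ci$lo, ci$p_hat); expect_gte(ci$hi, ci$p_hat)
  }
  # width shrinks with n at fixed p-hat
  w <- function(k, n) { ci <- wilson_ci(k, n); ci$hi - ci$lo }
  expect_gt(w(5, 20), w(25, 100))
  expect_gt(w(25, 100), w(250, 1000))
  expect_error(wilson_ci(3, 0), "positive")
})

test_that("Katz relative-risk CI is reciprocal-symmetric and handles zeros", {
  r <- risk_ratio(5, 50, 5, 50)
  expect_equal(r$rr, 1)
  expect_equal(r$lo * r$hi, 1, tolerance = 1e-12)  # symmetric about 1 on log scale
  # closed-form check
  r <- risk_ratio(2, 10, 4, 10)
  expect_equal(r$rr, 0.5)
  se <- sqrt(1 / 2 - 1 / 10 + 1 / 4 - 1 / 10)
  expect_equal(r$lo, exp(log(0.5) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r$hi, exp(log(0.5) + qnorm(0.975) * se), tolerance = 1e-12)
  # reciprocal symmetry
  set.seed(4)
  for (rep in 1:20) {
    n1 <- sample(10:80, 1); n2 <- sample(10:80, 1)
    k1 <- sample(1:n1, 1); k2 <- sample(1:n2, 1)
    a <- risk_ratio(k1, n1, k2, n2); b <- risk_ratio(k2, n2, k1, n1)
    expect_equal(a$rr * b$rr, 1, tolerance = 1e-12)
    expect_equal(a$lo, 1 / b$hi, tolerance = 1e-12)
  }
  expect_error(risk_ratio(3, 10, 0, 10), "undefined")
  z <- risk_ratio(0, 10, 3, 10)
  expect_equal(z$rr, 0)
  expect_false(z$ci_available)
})

test_that("uncorrected Pearson chi-square matches its closed form", {
  closed <- function(a, b, c, d) {
    N <- a + b + c + d
    N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  r <- pearson_chi2_2x2(20, 32, 6, 46)
  expect_equal(r$statistic, closed(20, 32, 6, 46), tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE))
  r <- pearson_chi2_2x2(10, 10, 10, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # invariance under swapping rows and under swapping columns
  set.seed(5)
  for (rep in 1:20) {
    x <- sample(1:40, 4, replace = TRUE)
    p0 <- pearson_chi2_2x2(x[1], x[2], x[3], x[4])$p_value
    expect_equal(pearson_chi2_2x2(x[3], x[4], x[1], x[2])$p_value, p0)
    expect_equal(pearson_chi2_2x2(x[2], x[1], x[4], x[3])$p_value, p0)
  }
  expect_error(pearson_chi2_2x2(0, 0, 3, 4), "zero margin")
})

test_that("unpaired t-test agrees with the pooled-variance closed form", {
  r <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  r <- unpaired_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(r$p_value, 0.01)
  expect_true(isTRUE(unpaired_t(c(2, 2, 2), c(2, 2, 2))$degenerate))
  set.seed(6)
  for (rep in 1:100) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    expect_equal(unpaired_t(x, y)$p_value, oracle_student_t(x, y),
                 tolerance = 1e-10)
  }
  # Welch variant is selectable and differs under variance heterogeneity
  x <- rnorm(10); y <- rnorm(40, sd = 5)
  expect_false(isTRUE(all.equal(unpaired_t(x, y, "welch")$p_value,
                                unpaired_t(x, y, "student")$p_value)))
})

test_that("Mann-Whitney U agrees with exhaustive enumeration for small samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  set.seed(8)
  for (n1 in 2:6) for (n2 in 2:6) {
    a <- runif(n1); b <- runif(n2, max = 1.4)  # continuous: no ties
    got <- mann_whitney_u(a, b)
    want <- oracle_mwu_exact(a, b)
    expect_equal(unname(got$statistic), want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  # normal approximation with continuity correction is close to exact at 7 vs 7
  for (rep in 1:5) {
    a <- runif(7); b <- runif(7, max = 1.3)
    approx_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(approx_p - oracle_mwu_exact(a, b)$p), 0.05)
  }
  # ties fall back to the corrected normal approximation
  r <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_equal(r$method, "mann_whitney_normal")
})

test_that("standardized mean differences match the balance-table formulas", {
  expect_equal(round(smd_continuous(21.8, 3.6, 21.6, 3.0), 2), 0.06)
  expect_equal(smd_continuous(5, 1, 5, 2), 0)
  expect_equal(smd_continuous(1, 1, 0, 1), 1)
  expect_equal(round(smd_binary(33 / 52, 31 / 52), 2), 0.08)
  expect_equal(round(smd_binary(10 / 52, 9 / 52), 2), 0.05)
  expect_equal(smd_binary(0.3, 0.3), 0)
  expect_error(smd_continuous(1, 0, 2, 0), "undefined")
  expect_error(smd_binary(0, 0), "undefined")
})

test_that("sample-size calculators match the normal-approximation formulas", {
  expect_identical(n_per_group_two_proportions(0.12, 0.36), 49L)
  # independent route: power.prop.test solves the same equation
  for (p in list(c(0.1, 0.3), c(0.2, 0.5), c(0.12, 0.36))) {
    ref <- ceiling(power.prop.test(p1 = p[1], p2 = p[2], power = 0.8)$n)
    expect_equal(n_per_group_two_proportions(p[1], p[2]), ref)
  }
  expect_identical(n_per_group_two_means(2.6, 3.9, 2.34, 2.37), 52L)
  expect_gte(n_per_group_two_means(2.6, 3.9, 2.34, 2.37, refine_t = TRUE), 52L)
  # monotonicity: in power, in variance, in effect
  expect_lt(n_per_group_two_proportions(0.1, 0.5, power = 0.5),
            n_per_group_two_proportions(0.1, 0.5, power = 0.8))
  expect_lt(n_per_group_two_means(0, 1, 1, 1),
            n_per_group_two_means(0, 1, 2, 2))
  expect_lt(n_per_group_two_means(0, 2, 1, 1),
            n_per_group_two_means(0, 1, 1, 1))
  # doubling both SDs quadruples the pre-ceiling n
  n_cont <- (qnorm(0.975) + qnorm(0.8))^2 * 2 / 1
  expect_equal(n_per_group_two_means(0, 1, 2, 2),
               as.integer(ceiling(4 * n_cont)))
  expect_identical(n_per_group_two_means(0, 100, 0.1, 0.1), 1L)
  expect_error(n_per_group_two_means(1, 1, 1, 1), "zero effect")
  expect_error(n_per_group_two_proportions(0.2, 0.2), "differ")
})

test_that("Bonferroni thresholds divide alpha by the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(round(bonferroni_threshold(0.05, 6), 3), 0.008)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})
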