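#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test for a binomial proportion. This is the interval
#' that reproduces every printed complication-rate CI in the trial tables to
#' the displayed digit (e.g. 6/52 -> 5.4--23.0%), which is how the method was
#' identified; it also has near-nominal coverage at moderate n, unlike the
#' Wald interval.
#'
#' @param k Number of events (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param level Confidence level, default 0.95.
#' @return A list of class `binomial_ci`: `k`, `n`, `level`, `p_hat`, `lo`,
#'   `hi` (proportions), `method = "wilson"`.
#' @examples
#' wilson_ci(6, 52)   # 11.5% [5.4, 23.0]
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (length(n) != 1 || n <= 0) stop("n must be a single positive count")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  z <- stats::qnorm((1 + level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(list(k = k, n = n, level = level, p_hat = p,
                 lo = max(0, center - half), hi = min(1, center + half),
                 method = "wilson"),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% [%d%% CI, %.1f-%.1f] (wilson)\n",
              x$k, x$n, 100 * x$p_hat, round(100 * x$level),
              100 * x$lo, 100 * x$hi))
  invisible(x)
}

#' Relative risk with Katz log-method confidence interval
#'
#' Point estimate \eqn{RR = (k_1/n_1)/(k_2/n_2)} with the confidence
#' interval built on the log scale,
#' \eqn{\exp(\log RR \pm z \sqrt{1/k_1 - 1/n_1 + 1/k_2 - 1/n_2})}.
#' Group 1 is the numerator (e.g. intervention), group 2 the reference.
#'
#' @param k1,n1 Events and trials in the numerator group.
#' @param k2,n2 Events and trials in the reference group.
#' @param level Confidence level, default 0.95.
#' @return A list of class `risk_ratio_result`: `rr`, `lo`, `hi`, `level`,
#'   `method = "katz"`. When `k1 = 0` the point estimate is 0 and the CI is
#'   `NA` with a flag `ci_available = FALSE`.
#' @examples
#' risk_ratio(6, 52, 20, 52)   # 0.30 [0.13, 0.69]
#' @export
risk_ratio <- function(k1, n1, k2, n2, level = 0.95) {
  if (k2 == 0) stop("k2 = 0: relative risk undefined (reference risk is 0)")
  rr <- (k1 / n1) / (k2 / n2)
  if (k1 == 0) {
    return(structure(list(rr = rr, lo = NA_real_, hi = NA_real_,
                          level = level, ci_available = FALSE,
                          method = "katz"),
                     class = "risk_ratio_result"))
  }
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(1 / k1 - 1 / n1 + 1 / k2 - 1 / n2)
  structure(list(rr = rr, lo = exp(log(rr) - z * se),
                 hi = exp(log(rr) + z * se), level = level,
                 ci_available = TRUE, method = "katz"),
            class = "risk_ratio_result")
}

#' @export
print.risk_ratio_result <- function(x, ...) {
  if (isTRUE(x$ci_available)) {
    cat(sprintf("relative risk %.2f [%d%% CI, %.2f-%.2f] (katz)\n",
                x$rr, round(100 * x$level), x$lo, x$hi))
  } else {
    cat(sprintf("relative risk %.2f (katz; CI unavailable, zero events)\n",
                x$rr))
  }
  invisible(x)
}

comparison_result <- function(endpoint, method, statistic, p_value,
                              alpha_adjusted = 0.05, estimate = NA_real_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(endpoint = endpoint, method = method,
                 statistic = unname(statistic), p_value = unname(p_value),
                 alpha_adjusted = alpha_adjusted, estimate = estimate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s statistic %.4g, p = %.4g (alpha = %.4g)\n",
              x$endpoint, x$method, x$statistic, x$p_value, x$alpha_adjusted))
  invisible(x)
}

#' Uncorrected Pearson chi-square test on a 2x2 table
#'
#' \eqn{\chi^2 = N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} on 1 degree of
#' freedom, without the Yates continuity correction: the uncorrected
#' statistic is the one that reproduces the trial's printed complication
#' p-values (0.002 and 0.047); the corrected one does not.
#'
#' @param a,b First row of the table (e.g. events / non-events, group 1).
#' @param c,d Second row (group 2).
#' @param endpoint Label carried into the result.
#' @param alpha_adjusted Significance threshold to record alongside.
#' @return A `comparison_result` with `method = "pearson_chi2_uncorrected"`.
#' @examples
#' pearson_chi2_2x2(20, 32, 6, 46)   # p = 0.0015
#' @export
pearson_chi2_2x2 <- function(a, b, c, d, endpoint = "2x2",
                             alpha_adjusted = 0.05) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  comparison_result(endpoint, "pearson_chi2_uncorrected",
                    ct$statistic, ct$p.value, alpha_adjusted)
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance t-test by default (the trial reports only
#' "unpaired t-test"); Welch's unequal-variance form is selectable. The
#' degenerate case of two identical constant samples returns p = 1 with a
#' `degenerate` flag rather than NaN.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @param endpoint Label carried into the result.
#' @param alpha_adjusted Significance threshold to record alongside.
#' @return A `comparison_result` with `method = "t_student"` or `"t_welch"`,
#'   `estimate` = mean difference a - b.
#' @export
unpaired_t <- function(sample_a, sample_b, variant = c("student", "welch"),
                       endpoint = "continuous", alpha_adjusted = 0.05) {
  variant <- match.arg(variant)
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  est <- mean(sample_a) - mean(sample_b)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    res <- comparison_result(endpoint, paste0("t_", variant),
                             statistic = 0,
                             p_value = if (est == 0) 1 else 0,
                             alpha_adjusted, estimate = est)
    res$degenerate <- TRUE
    return(res)
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = (variant == "student"))
  comparison_result(endpoint, paste0("t_", variant), tt$statistic,
                    tt$p.value, alpha_adjusted, estimate = est)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with mid-ranks for ties. The exact permutation distribution
#' is used when both samples have at most 8 observations and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is used. The U statistic reported is the number of
#' (a, b) pairs with a > b (plus half the ties).
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 1.
#' @param endpoint Label carried into the result.
#' @param alpha_adjusted Significance threshold to record alongside.
#' @return A `comparison_result` with `method = "mann_whitney_exact"` or
#'   `"mann_whitney_normal"`, `statistic` = U.
#' @export
mann_whitney_u <- function(sample_a, sample_b, endpoint = "ordinal",
                           alpha_adjusted = 0.05) {
  stopifnot(length(sample_a) >= 1, length(sample_b) >= 1)
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- length(sample_a) <= 8 && length(sample_b) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  comparison_result(endpoint,
                    if (exact) "mann_whitney_exact" else "mann_whitney_normal",
                    wt$statistic, wt$p.value, alpha_adjusted)
}

#' Standardized mean difference for continuous variables
#'
#' Baseline-balance statistic \eqn{|m_1 - m_2| / \sqrt{(sd_1^2 + sd_2^2)/2}}.
#' Values above 0.1 are conventionally flagged as imbalance.
#'
#' @param m1,sd1 Mean and SD in group 1.
#' @param m2,sd2 Mean and SD in group 2.
#' @return The (non-negative) standardized mean difference.
#' @examples
#' smd_continuous(21.8, 3.6, 21.6, 3.0)  # 0.06
#' @export
smd_continuous <- function(m1, sd1, m2, sd2) {
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop("both SDs are 0: SMD undefined")
  abs(m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Standardized mean difference for binary variables
#'
#' Proportion analogue of [smd_continuous()]:
#' \eqn{|p_1 - p_2| / \sqrt{(p_1(1-p_1) + p_2(1-p_2))/2}}.
#'
#' @param p1,p2 Proportions in the two groups.
#' @return The standardized mean difference.
#' @examples
#' smd_binary(33/52, 31/52)  # 0.08
#' @export
smd_binary <- function(p1, p2) {
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) stop("proportions must be in [0, 1]")
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (v == 0) stop("zero pooled variance: SMD undefined")
  abs(p1 - p2) / sqrt(v)
}

#' Per-group sample size for comparing two proportions
#'
#' Uncorrected normal-approximation formula
#' \deqn{n = \lceil (z_{1-\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_{1-\beta}\sqrt{p_1 q_1 + p_2 q_2})^2 / (p_1 - p_2)^2 \rceil}
#' with \eqn{\bar p = (p_1 + p_2)/2}. No continuity correction; the result
#' is always rounded up, since a sample size must guarantee the power.
#'
#' @param p1,p2 Anticipated event probabilities, both in (0, 1), unequal.
#' @param alpha Two-sided type-I error, default 0.05.
#' @param power Target power, default 0.8.
#' @return Integer sample size per group.
#' @examples
#' n_per_group_two_proportions(0.12, 0.36)  # 49
#' @export
n_per_group_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.8) {
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) stop("p1, p2 must be in (0, 1)")
  if (p1 == p2) stop("p1 must differ from p2")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pb <- (p1 + p2) / 2
  num <- (za * sqrt(2 * pb * (1 - pb)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  as.integer(ceiling(num / (p1 - p2)^2))
}

#' Per-group sample size for comparing two means
#'
#' Normal-approximation formula
#' \eqn{n = \lceil (z_{1-\alpha/2} + z_{1-\beta})^2 (sd_1^2 + sd_2^2) /
#' (m_1 - m_2)^2 \rceil}. An iterative refinement replacing the normal
#' quantiles with t quantiles at 2n - 2 degrees of freedom is selectable;
#' it typically adds one to two participants per group at moderate n.
#'
#' @param m1,m2 Anticipated group means (unequal).
#' @param sd1,sd2 Anticipated SDs (> 0).
#' @param alpha Two-sided type-I error, default 0.05.
#' @param power Target power, default 0.8.
#' @param refine_t If `TRUE`, iterate with t quantiles until stable.
#' @return Integer sample size per group.
#' @examples
#' n_per_group_two_means(2.6, 3.9, 2.34, 2.37)  # 52
#' @export
n_per_group_two_means <- function(m1, m2, sd1, sd2, alpha = 0.05,
                                  power = 0.8, refine_t = FALSE) {
  if (m1 == m2) stop("zero effect: sample size undefined")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be > 0")
  vsum <- sd1^2 + sd2^2
  delta2 <- (m1 - m2)^2
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- ceiling((za + zb)^2 * vsum / delta2)
  if (refine_t) {
    repeat {
      df <- max(2 * n - 2, 2)
      n_new <- ceiling((stats::qt(1 - alpha / 2, df) +
                        stats::qt(power, df))^2 * vsum / delta2)
      if (n_new <= n) break
      n <- n_new
    }
  }
  as.integer(n)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate, default 0.05.
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 2)  # 0.025, the co-primary threshold
#' bonferroni_threshold(0.05, 6)  # 0.00833..., the timepoint threshold
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}
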