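# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# logistic NR via stats::plogis (independent of the hand-written transform)
oracle_nr <- function(s) pmax(2 * stats::plogis(s) - 1, 0)

# explicit forward-fill oracle: fill SBP first, then apply the formula
oracle_nr_trace <- function(samples) {
  first <- match(FALSE, is.na(samples$sbp))
  s <- samples[seq(first, nrow(samples)), ]
  filled <- s$sbp
  for (i in seq_along(filled)) {
    if (is.na(filled[i])) filled[i] <- filled[i - 1]
  }
  data.frame(t = s$t,
             nr = oracle_nr(0.01 * s$hr + 0.02 * filled - 0.17 * s$pi),
             sbp_carried = is.na(s$sbp))
}

# exhaustive Mann-Whitney two-sided p by enumerating all group assignments
oracle_mwu_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# pooled-variance two-sample t-test from first principles
oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tstat), n1 + n2 - 2)
}

# small, fast simulator configuration for structural/determinism tests
quick_config <- function(seed = 1, n_per_arm = 4) {
  sim_config(n_per_arm = n_per_arm, seed = seed,
             duration = list(mean = 60, sd = 10, min = 40, max = 80))
}

# a hand-built series: constant HR/PI, cuff SBP at t = 0 and t = 5 only
carry_series <- function() {
  vital_series("p1",
               data.frame(t = 0:5, hr = 70,
                          sbp = c(120, NA, NA, NA, NA, 140), pi = 2.0),
               events = c(surgery_start = 0L, surgery_end = 5L))
}
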