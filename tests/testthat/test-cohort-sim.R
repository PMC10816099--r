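test_that("simulation is deterministic and extensible in n_per_arm", {
  ds1 <- simulate_trial(quick_config(seed = 9))
  ds2 <- simulate_trial(quick_config(seed = 9))
  expect_identical(trial_outcomes(ds1), trial_outcomes(ds2))
  expect_identical(trial_summaries(ds1), trial_summaries(ds2))
  d1 <- tempfile(); d2 <- tempfile()
  write_trial_csv(ds1, d1); write_trial_csv(ds2, d2)
  for (f in c("vitals.csv", "events.csv", "nr_traces.csv", "outcomes.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
  # patient counts, and per-patient substreams: growing the trial does not
  # reshuffle earlier patients
  expect_length(ds1$patients, 8)
  ds_big <- simulate_trial(quick_config(seed = 9, n_per_arm = 6))
  expect_length(ds_big$patients, 12)
  o_small <- trial_outcomes(ds1)
  o_big <- trial_outcomes(ds_big)
  shared <- o_small$patient_id
  expect_identical(o_small, o_big[match(shared, o_big$patient_id), ],
                   ignore_attr = TRUE)
})

test_that("with no noise and no events the NR trace sits at the baseline fixed point", {
  cfg <- sim_config(
    baseline = list(hr_mean = 62, hr_sd = 0, sbp_mean = 105, sbp_sd = 0,
                    pi_mean = 5, pi_sd = 0),
    stimulus = list(awake_drive = 0, surgical_drive = 0,
                    surgical_drive_sd = 0, intubation_mag = 0,
                    intubation_tau = 3, incision_mag = 0, incision_tau = 4,
                    pneumo_onset_lag = 2, pneumo_rise_tau = 3,
                    closure_mag = 0, closure_tau = 5, closure_before_end = 8,
                    emergence_drive = 0),
    noise = list(sd = 0, corr_time = 8),
    duration = list(mean = 60, sd = 0, min = 60, max = 60))
  vs <- simulate_vitals("control", cfg, seed = 1, controller = FALSE)
  tr <- nr_from_vitals(vs)
  expect_equal(unique(tr$nr), compute_nr(compute_stimulus(62, 105, 5)),
               tolerance = 1e-12)
})

test_that("controller can only lower NR: paired trajectories share the stimulus", {
  cfg <- sim_config(duration = list(mean = 120, sd = 20, min = 80, max = 160))
  for (seed in c(2, 17, 301)) {
    stim <- simulate_stimulus("nr_guided", cfg, seed = seed)
    off <- nr_from_vitals(simulate_vitals("nr_guided", cfg, stimulus = stim,
                                          controller = FALSE))
    on <- nr_from_vitals(simulate_vitals("nr_guided", cfg, stimulus = stim,
                                         controller = TRUE))
    expect_true(all(on$nr <= off$nr + 1e-9))
    w <- c(stim$events[["surgery_start"]], stim$events[["surgery_end"]])
    in_w <- on$t >= w[1] & on$t <= w[2]
    expect_lte(mean(on$nr[in_w] >= 0.85), mean(off$nr[in_w] >= 0.85))
  }
})

test_that("controller effect follows the first-order recursion in closed form", {
  cc <- sim_config()$controller
  # idle below threshold: the reactive effects stay 0; only the documented
  # prophylactic baseline reduction remains
  st <- controller_init()
  for (i in 1:20) st <- controller_step(st, 0.5, cc)
  expect_equal(st$e1, 0); expect_equal(st$e2, 0)
  expect_equal(st$reduction, cc$baseline_effect)
  expect_false(st$engaged_secondary)
  # with no prophylactic component, drive passes through untouched
  cc0 <- cc; cc0$baseline_effect <- 0
  st <- controller_init()
  for (i in 1:20) st <- controller_step(st, 0.5, cc0)
  expect_equal(st$reduction, 0)
  # sustained exceedance: e1_k = 1 - (1 - 1/lag)^k, secondary only after
  # the persistence window
  st <- controller_init()
  for (k in 1:(cc$persistence - 1)) {
    st <- controller_step(st, 0.95, cc)
    expect_equal(st$e1, 1 - (1 - 1 / cc$effect_lag)^k, tolerance = 1e-12)
    expect_false(st$engaged_secondary)
  }
  st <- controller_step(st, 0.95, cc)
  expect_true(st$engaged_secondary)
})

test_that("a step disturbance is pulled back below threshold at the predicted minute", {
  cfg <- sim_config()
  g <- with(cfg$gains, 0.01 * hr + 0.02 * sbp + 0.17 * pi)
  s_base <- with(cfg$baseline, 0.01 * hr_mean + 0.02 * sbp_mean - 0.17 * pi_mean)
  s_target <- log((1 + 0.90) / (1 - 0.90))       # drive NR to 0.90
  u_star <- (s_target - s_base) / g
  n_min <- 40
  stim <- list(arm = "nr_guided", hr_base = cfg$baseline$hr_mean,
               sbp_base = cfg$baseline$sbp_mean, pi_base = cfg$baseline$pi_mean,
               invasive = TRUE, gain_mult = 1,
               u0 = rep(u_star, n_min + 1),
               events = c(T0 = 0L, T1 = 0L, T2 = 0L, T3 = 1L, T4 = 2L,
                          surgery_start = 2L, T5 = as.integer(n_min),
                          surgery_end = as.integer(n_min),
                          T6 = as.integer(n_min)))
  tr <- nr_from_vitals(simulate_vitals("nr_guided", cfg, stimulus = stim,
                                       controller = TRUE))
  # closed form: NR_t uses the reduction after t updates-so-far (baseline
  # component plus the lagged reactive effect); first minute below threshold
  s_thr <- log((1 + cfg$controller$threshold) / (1 - cfg$controller$threshold))
  k <- 0:n_min
  e1 <- 1 - (1 - 1 / cfg$controller$effect_lag)^k
  red <- ifelse(k == 0, 0,
                cfg$controller$baseline_effect +
                  cfg$controller$effect_gain * e1)
  predicted <- min(k[s_target - g * red < s_thr])
  expect_lt(predicted, cfg$controller$persistence)  # primary stage suffices
  observed <- min(tr$t[tr$nr < cfg$controller$threshold])
  expect_equal(observed, predicted)
})

test_that("outcome models degenerate and recover their generating parameters", {
  cfg <- sim_config()
  # degenerate: no slope, no noise -> CRP pinned at the (truncated) intercept
  cfg0 <- cfg; cfg0$outcome$crp_slope <- 0; cfg0$outcome$crp_sd <- 0
  out <- simulate_outcomes(runif(50, 0.6, 0.9), "control", cfg0, seed = 1)
  expect_true(all(out$crp_pod1 == max(0, cfg0$outcome$crp_intercept)))
  # complication grades: III only via grade3_share, never in the guided arm
  m <- runif(2000, 0.75, 0.95)
  oc <- simulate_outcomes(m, "control", cfg, seed = 2)
  on <- simulate_outcomes(m, "nr_guided", cfg, seed = 3)
  expect_true(all(oc$clavien_dindo[oc$complication] %in% c("II", "III")))
  expect_false(any(on$clavien_dindo == "III"))
  expect_true(all(oc$complication == (oc$clavien_dindo != "0")))

  # logit-linear slope recovery on a 5,000-patient cohort
  set.seed(11)
  m <- runif(5000, 0.65, 0.92)
  out <- simulate_outcomes(m, "control", cfg, seed = 12)
  fit <- glm(out$complication ~ m, family = binomial())
  ci <- coef(fit)[2] + c(-1, 1) * 1.96 * sqrt(vcov(fit)[2, 2])
  expect_gt(cfg$outcome$comp_slope, ci[1])
  expect_lt(cfg$outcome$comp_slope, ci[2])

  # CRP slope recovery by censored-normal (tobit) maximum likelihood,
  # respecting the truncation at 0
  nll <- function(par) {
    mu <- par[1] + par[2] * m; s <- exp(par[3])
    -sum(ifelse(out$crp_pod1 > 0,
                dnorm(out$crp_pod1, mu, s, log = TRUE),
                pnorm(0, mu, s, log.p = TRUE)))
  }
  fit <- optim(c(-10, 18, 1), nll, hessian = TRUE)
  se_b <- sqrt(solve(fit$hessian)[2, 2])
  expect_gt(cfg$outcome$crp_slope, fit$par[2] - 1.96 * se_b)
  expect_lt(cfg$outcome$crp_slope, fit$par[2] + 1.96 * se_b)
  # complication probability increases with nociception burden
  br <- cut(m, quantile(m, seq(0, 1, 0.25)), include.lowest = TRUE)
  rates <- tapply(out$complication, br, mean)
  expect_true(all(diff(rates) > -0.05))
})

test_that("cuff cadence: non-invasive SBP every 5 minutes, invasive every minute", {
  cfg <- sim_config(invasive_frac = c(control = 0, nr_guided = 1),
                    duration = list(mean = 60, sd = 0, min = 60, max = 60))
  vs_cuff <- simulate_vitals("control", cfg, seed = 5)
  obs <- vs_cuff$samples$t[!is.na(vs_cuff$samples$sbp)]
  expect_true(all(obs %% 5 == 0))
  expect_true(any(nr_from_vitals(vs_cuff)$sbp_carried))
  vs_art <- simulate_vitals("nr_guided", cfg, seed = 5)
  expect_false(any(is.na(vs_art$samples$sbp)))
  # annotated timepoints exist on the grid and in order
  ev <- vs_cuff$events
  expect_true(all(diff(ev[paste0("T", 0:6)]) >= 0))
})

test_that("with guidance disabled in both arms the arms are exchangeable", {
  reps <- 60
  ns <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- quick_config(seed = 1000 + r, n_per_arm = 8)
    cfg$controller$enabled <- FALSE
    s <- trial_summaries(simulate_trial(cfg))
    p <- unpaired_t(s$mean_nr[s$arm == "control"],
                    s$mean_nr[s$arm == "nr_guided"])$p_value
    ns[r] <- p > 0.05
  }
  expect_gte(mean(ns), 0.9)
})

test_that("config validation lists offending fields and rejects bad configs", {
  expect_error(sim_config(n_per_arm = 0), "n_per_arm")
  expect_error(sim_config(controller = list(enabled = TRUE, threshold = 1.2)),
               "threshold")
  cfg <- quick_config()
  cfg$noise$sd <- -1
  expect_error(simulate_trial(cfg), "SDs")
})

test_that("a config file round-trips through JSON and YAML", {
  cfg <- sim_config(n_per_arm = 7, seed = 123)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  back <- read_sim_config(f)
  expect_equal(back$n_per_arm, 7L)
  expect_equal(back$controller, cfg$controller, tolerance = 1e-12)
  expect_identical(trial_outcomes(simulate_trial(quick_config(seed = 123))),
                   trial_outcomes(simulate_trial(quick_config(seed = 123))))
  skip_if_not_installed("yaml")
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), fy)
  expect_equal(read_sim_config(fy)$outcome$crp_slope, cfg$outcome$crp_slope)
  unlink(c(f, fy))
})
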