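# Simulator model: each patient carries a latent nociceptive drive u(t) on
# the 1-minute grid (awake plateau, event pulses, sustained surgical plateau,
# emergence rise, AR(1) noise). Vitals are affine in the drive, so the
# stimulus term S is affine in it too. The controller observes the measured
# NR (carried-forward cuff pressure included) and subtracts a lagged
# anti-nociceptive effect from the drive.

sim_version <- "nociguard-sim-1"

# Independent per-patient substream: a fixed arithmetic hash of
# (root seed, arm, patient index), so datasets extend without reshuffling.
patient_seed <- function(root, arm, index) {
  off <- if (arm == "control") 0 else 1
  as.integer(((root %% 59999) * 31607 + off * 15991 + index * 7919) %%
               2147483647)
}

#' Draw the per-patient stimulus stream
#'
#' Generates every random component of one patient's trajectory --
#' anesthetized baseline vitals, monitoring mode, event timeline, surgical
#' drive intensity and the mean-reverting noise path -- but applies no
#' controller. The same stream can then be rendered with the controller on
#' or off ([simulate_vitals()]), which is how paired controller-dominance
#' comparisons are made.
#'
#' @param arm `"control"` or `"nr_guided"` (sets the invasive-monitoring
#'   fraction; the controller is chosen later).
#' @param config A [sim_config()].
#' @param seed Integer seed for this patient's substream.
#' @return A list with the baseline vitals, `invasive` flag, `events`
#'   vector, and the uncontrolled drive path `u0` over minutes `0..t_end`.
#' @export
simulate_stimulus <- function(arm = c("control", "nr_guided"),
                              config = sim_config(), seed = 1) {
  arm <- match.arg(arm)
  set.seed(seed)
  bl <- config$baseline
  tl <- config$timeline
  st <- config$stimulus

  hr_b <- stats::rnorm(1, bl$hr_mean, bl$hr_sd)
  sbp_b <- stats::rnorm(1, bl$sbp_mean, bl$sbp_sd)
  pi_b <- max(1, stats::rnorm(1, bl$pi_mean, bl$pi_sd))
  invasive <- stats::runif(1) < config$invasive_frac[[arm]]

  dur <- round(min(config$duration$max,
                   max(config$duration$min,
                       stats::rnorm(1, config$duration$mean,
                                    config$duration$sd))))
  t4 <- sample(tl$t4_min:tl$t4_max, 1)
  t3 <- t4 - sample(tl$t3_gap_min:tl$t3_gap_max, 1)
  t5 <- t4 + dur
  t6 <- t5 + sample(tl$t6_min:tl$t6_max, 1)
  surg_drive <- max(0, stats::rnorm(1, st$surgical_drive,
                                    st$surgical_drive_sd))
  # heterogeneity in how vigorously NR-guided care is titrated
  gain_mult <- max(0, stats::rnorm(1, 1, config$controller$gain_sd))

  tt <- 0:t6
  u0 <- numeric(length(tt))
  u0[tt < tl$t1] <- st$awake_drive
  pulse <- function(t_on, mag, tau) {
    ifelse(tt >= t_on, mag * exp(-(tt - t_on) / tau), 0)
  }
  u0 <- u0 + pulse(tl$t2, st$intubation_mag, st$intubation_tau)
  u0 <- u0 + pulse(t4, st$incision_mag, st$incision_tau)
  # sustained pneumoperitoneum/dissection plateau, released at surgery end
  on <- t4 + st$pneumo_onset_lag
  plateau <- ifelse(tt >= on & tt <= t5,
                    surg_drive * (1 - exp(-(tt - on) / st$pneumo_rise_tau)),
                    0)
  plateau[tt > t5] <- surg_drive * exp(-(tt[tt > t5] - t5) / 3)
  u0 <- u0 + plateau
  cl <- t5 - st$closure_before_end
  if (cl > t4) u0 <- u0 + pulse(cl, st$closure_mag, st$closure_tau)
  u0[tt > t5] <- u0[tt > t5] +
    st$emergence_drive * (1 - exp(-(tt[tt > t5] - t5) / 3))

  a <- exp(-1 / config$noise$corr_time)
  innov <- stats::rnorm(length(tt), 0, config$noise$sd * sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1, 0, config$noise$sd)
  u0 <- u0 + as.numeric(stats::filter(innov, a, method = "recursive"))

  list(arm = arm, hr_base = hr_b, sbp_base = sbp_b, pi_base = pi_b,
       invasive = invasive, u0 = u0, gain_mult = gain_mult,
       events = c(T0 = 0L, T1 = as.integer(tl$t1), T2 = as.integer(tl$t2),
                  T3 = as.integer(t3), T4 = as.integer(t4),
                  surgery_start = as.integer(t4), T5 = as.integer(t5),
                  surgery_end = as.integer(t5), T6 = as.integer(t6)))
}

#' One step of the closed-loop anti-nociceptive controller
#'
#' Emulates the clinician response of NR-guided care: while the measured NR
#' is at or above the threshold, the primary (opioid-like) effect rises
#' toward `effect_max` with first-order lag `effect_lag`; when NR is below
#' threshold it decays with `decay_lag`. A secondary (landiolol-like) stage
#' engages only after `persistence` consecutive minutes of exceedance and
#' decays with `secondary_decay`. The drive reduction returned is
#' `effect_gain * e1 + secondary_gain * e2`, always non-negative, so a
#' controlled trajectory can never exceed its uncontrolled twin.
#'
#' @param state List with `e1`, `e2`, `streak`, `engaged_secondary`; use
#'   `controller_init()` to start.
#' @param nr_current Measured NR index this minute.
#' @param controller The `controller` block of a [sim_config()].
#' @param active Whether the controller may respond this minute (it is held
#'   inactive before intubation and only decays after surgery end).
#' @param gain_mult Per-patient multiplier on the effect gains (>= 0),
#'   modelling variation in how vigorously care is titrated.
#' @return Updated state, with element `reduction` (drive units to subtract
#'   next minute).
#' @export
controller_step <- function(state, nr_current, controller, active = TRUE,
                            gain_mult = 1) {
  cc <- controller
  base <- if (active) cc$baseline_effect %||% 0 else 0
  if (active && nr_current >= cc$threshold) {
    state$e1 <- state$e1 + (cc$effect_max - state$e1) / cc$effect_lag
    state$streak <- state$streak + 1L
  } else {
    state$e1 <- state$e1 * (1 - 1 / cc$decay_lag)
    state$streak <- 0L
  }
  if (active && state$streak >= cc$persistence) {
    state$e2 <- state$e2 + (cc$effect_max - state$e2) / cc$secondary_lag
    state$engaged_secondary <- TRUE
  } else {
    state$e2 <- state$e2 * (1 - 1 / cc$secondary_decay)
  }
  state$reduction <- gain_mult *
    (base + cc$effect_gain * state$e1 + cc$secondary_gain * state$e2)
  state
}

#' @rdname controller_step
#' @export
controller_init <- function() {
  list(e1 = 0, e2 = 0, streak = 0L, engaged_secondary = FALSE, reduction = 0)
}

#' Simulate one patient's per-minute vital-sign series
#'
#' Renders a stimulus stream into measured vitals: heart rate and perfusion
#' index every minute, systolic pressure every minute under invasive
#' monitoring or every 5 minutes otherwise (the cuff cadence), with the
#' closed-loop controller in the NR-guided arm acting on the measured NR
#' (i.e. on the carried-forward pressure, exactly what the monitor
#' displays).
#'
#' @param arm `"control"` or `"nr_guided"`.
#' @param config A [sim_config()].
#' @param seed Integer seed for this patient's substream (ignored when
#'   `stimulus` is supplied).
#' @param stimulus Optional pre-drawn stream from [simulate_stimulus()],
#'   for paired controller-on/off comparisons.
#' @param controller Logical; defaults to `TRUE` in the NR-guided arm when
#'   `config$controller$enabled` is `TRUE`.
#' @return A [vital_series] with attributes `landiolol_used` (logical) and
#'   `controller` (logical).
#' @export
simulate_vitals <- function(arm = c("control", "nr_guided"),
                            config = sim_config(), seed = 1,
                            stimulus = NULL,
                            controller = identical(arm, "nr_guided") &&
                              isTRUE(config$controller$enabled %||% TRUE)) {
  arm <- match.arg(arm)
  if (is.null(stimulus)) stimulus <- simulate_stimulus(arm, config, seed)
  st <- stimulus
  cc <- config$controller
  g <- config$gains
  t2 <- st$events[["T2"]]
  t5 <- st$events[["surgery_end"]]
  n <- length(st$u0)
  tt <- seq_len(n) - 1L

  hr <- pi_ <- sbp_true <- rep(NA_real_, n)
  sbp_rec <- rep(NA_real_, n)
  cstate <- controller_init()
  last_sbp <- NA_real_
  for (i in seq_len(n)) {
    t <- tt[i]
    u <- st$u0[i] - if (controller) cstate$reduction else 0
    hr[i] <- max(30, st$hr_base + g$hr * u)
    sbp_true[i] <- max(50, st$sbp_base + g$sbp * u)
    pi_[i] <- max(0.3, st$pi_base - g$pi * u)
    fresh <- st$invasive || t %% 5L == 0L
    if (fresh) last_sbp <- sbp_true[i]
    if (fresh || !is.na(last_sbp)) sbp_rec[i] <- if (fresh) sbp_true[i] else NA
    nr_t <- compute_nr(compute_stimulus(hr[i], last_sbp, pi_[i]))
    if (controller) {
      cstate <- controller_step(cstate, nr_t, cc,
                                active = (t >= t2 && t <= t5),
                                gain_mult = st$gain_mult %||% 1)
    }
  }
  vs <- vital_series(
    patient_id = NA_character_,
    samples = data.frame(t = tt, hr = hr, sbp = sbp_rec, pi = pi_,
                         sbp_source = ifelse(is.na(sbp_rec), NA_character_,
                                             if (st$invasive) "invasive"
                                             else "noninvasive")),
    events = st$events,
    pre_anesthesia_sbp = sbp_true[1])
  attr(vs, "landiolol_used") <- isTRUE(cstate$engaged_secondary)
  attr(vs, "controller") <- controller
  attr(vs, "invasive") <- st$invasive
  vs
}

#' Simulate postoperative outcomes from intraoperative nociception burden
#'
#' Outcomes depend on the arm only through the per-patient mean NR (and,
#' for the grade split, the arm's conditional grade-III share): POD-1 CRP
#' is linear in mean NR with Gaussian noise truncated at 0; a complication
#' (Clavien-Dindo grade >= II) is Bernoulli with logit-linear probability in
#' mean NR; conditionally on a complication the grade is III with the arm's
#' `grade3_share`, otherwise II; the POD-1 pain score (NRS) is a rounded,
#' clamped latent Gaussian shifted by mean NR.
#'
#' @param mean_nr Numeric vector of per-patient mean NR values.
#' @param arm `"control"` or `"nr_guided"` (grade split only).
#' @param config A [sim_config()].
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Data frame with columns `crp_pod1`, `complication` (logical),
#'   `clavien_dindo` (`"0"`, `"II"` or `"III"`), `nrs_pod1` (integer 0-10).
#' @export
simulate_outcomes <- function(mean_nr, arm = c("control", "nr_guided"),
                              config = sim_config(), seed = NULL) {
  arm <- match.arg(arm)
  if (!is.null(seed)) set.seed(seed)
  oc <- config$outcome
  n <- length(mean_nr)
  crp <- pmax(0, oc$crp_intercept + oc$crp_slope * mean_nr +
                 stats::rnorm(n, 0, oc$crp_sd))
  p_comp <- stats::plogis(oc$comp_intercept + oc$comp_slope * mean_nr)
  comp <- stats::runif(n) < p_comp
  g3 <- stats::runif(n) < oc$grade3_share[[arm]]
  grade <- ifelse(comp, ifelse(g3, "III", "II"), "0")
  nrs <- pmin(10, pmax(0, round(oc$nrs_intercept + oc$nrs_slope * mean_nr +
                                  stats::rnorm(n, 0, oc$nrs_sd))))
  data.frame(crp_pod1 = crp, complication = comp, clavien_dindo = grade,
             nrs_pod1 = as.integer(nrs))
}

#' Simulate a complete two-arm trial
#'
#' Draws `n_per_arm` patients in each arm from independent per-patient
#' substreams of the root seed, runs the per-minute NR computation
#' ([nr_from_vitals()]) on every simulated series, summarises each patient
#' over the surgical window ([summarize_nr()]), and draws outcomes from the
#' per-patient mean NR. Deterministic: the same config (including seed)
#' yields an identical dataset.
#'
#' @param config A [sim_config()].
#' @return An object of class `trial_dataset`: list with `config`,
#'   `patients` (list of per-patient records, each holding `patient_id`,
#'   `arm`, `vitals`, `nr_trace`, `nr_summary`, the outcome fields and a
#'   `landiolol` flag) and `provenance`.
#' @export
simulate_trial <- function(config = sim_config()) {
  validate_sim_config(config)
  patients <- list()
  for (arm in c("control", "nr_guided")) {
    for (i in seq_len(config$n_per_arm)) {
      ps <- patient_seed(config$seed, arm, i)
      vs <- simulate_vitals(arm, config, seed = ps)
      pid <- sprintf("%s_%03d", if (arm == "control") "C" else "N", i)
      vs$patient_id <- pid
      trace <- nr_from_vitals(vs, threshold = config$controller$threshold)
      attr(trace, "patient_id") <- pid
      summ <- summarize_nr(trace, vs$events,
                           threshold = config$controller$threshold,
                           patient_id = pid)
      out <- simulate_outcomes(summ$mean_nr, arm, config,
                               seed = ps + 1L)
      patients[[pid]] <- list(
        patient_id = pid, arm = arm, vitals = vs, nr_trace = trace,
        nr_summary = summ, crp_pod1 = out$crp_pod1,
        complication = out$complication,
        clavien_dindo = out$clavien_dindo,
        nrs_pod1 = out$nrs_pod1,
        landiolol = isTRUE(attr(vs, "landiolol_used")),
        invasive = isTRUE(attr(vs, "invasive")))
    }
  }
  structure(list(config = config, patients = patients,
                 provenance = list(seed = config$seed,
                                   generator = sim_version)),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  arms <- vapply(x$patients, `[[`, "", "arm")
  cat("<trial_dataset>", length(x$patients), "patients (",
      sum(arms == "control"), "control /", sum(arms == "nr_guided"),
      "NR-guided ), seed", x$provenance$seed, "\n")
  invisible(x)
}

#' Per-patient summary and outcome tables of a simulated trial
#'
#' `trial_summaries()` returns one row per patient with the intraoperative
#' NR summary; `trial_outcomes()` returns the outcome table (the analysis
#' surface of the trial pipeline).
#'
#' @param dataset A `trial_dataset` from [simulate_trial()].
#' @return A data frame, one row per patient.
#' @export
trial_summaries <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  do.call(rbind, lapply(dataset$patients, function(p) {
    s <- p$nr_summary
    tp <- s$timepoint_nr
    tps <- stats::setNames(rep(NA_real_, 7), paste0("T", 0:6))
    tps[names(tp)] <- tp
    cbind(data.frame(patient_id = p$patient_id, arm = p$arm,
                     highest_nr = s$highest_nr, mean_nr = s$mean_nr,
                     lowest_nr = s$lowest_nr,
                     frac_above_threshold = s$frac_above_threshold,
                     duration_min = unname(p$vitals$events["surgery_end"] -
                                           p$vitals$events["surgery_start"]),
                     invasive = p$invasive, landiolol = p$landiolol,
                     row.names = NULL),
          as.data.frame(as.list(tps)))
  }))
}

#' @rdname trial_summaries
#' @export
trial_outcomes <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  do.call(rbind, lapply(dataset$patients, function(p) {
    data.frame(patient_id = p$patient_id, arm = p$arm,
               mean_nr = p$nr_summary$mean_nr, crp_pod1 = p$crp_pod1,
               clavien_dindo = p$clavien_dindo,
               complication = p$complication, nrs_pod1 = p$nrs_pod1,
               row.names = NULL)
  }))
}

#' Write a simulated trial to CSV files
#'
#' Writes `vitals.csv`, `events.csv`, `nr_traces.csv`, `outcomes.csv` and
#' `summaries.csv` under `out_dir`, in the long formats read back by
#' [read_vitals_csv()] and [analyze_trial()].
#'
#' @param dataset A `trial_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_trial_csv <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- lapply(dataset$patients, `[[`, "vitals")
  f_v <- file.path(out_dir, "vitals.csv")
  f_e <- file.path(out_dir, "events.csv")
  write_vitals_csv(series, f_v, f_e)
  f_t <- file.path(out_dir, "nr_traces.csv")
  write_nr_trace(lapply(dataset$patients, `[[`, "nr_trace"), f_t)
  f_o <- file.path(out_dir, "outcomes.csv")
  utils::write.csv(trial_outcomes(dataset), f_o, row.names = FALSE)
  f_s <- file.path(out_dir, "summaries.csv")
  utils::write.csv(trial_summaries(dataset), f_s, row.names = FALSE)
  invisible(c(f_v, f_e, f_t, f_o, f_s))
}
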