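#' Configuration for the synthetic two-arm trial simulator
#'
#' Builds the full parameter set of the cohort simulator. The defaults are
#' calibrated once so that, at n = 52 per arm, the simulated control arm has
#' per-patient mean NR centred on 0.809 (between-patient SD ~0.047), the
#' NR-guided arm (closed-loop controller on) on 0.753 (SD ~0.060),
#' complication rates near 38.5% and 11.5%, and POD-1 CRP means near 3.66
#' and 2.70 mg/dL. See the package vignette for the calibration rationale.
#'
#' @param n_per_arm Patients per arm (default 52).
#' @param seed Root seed; every patient derives an independent substream
#'   from it, so increasing `n_per_arm` does not reshuffle earlier patients.
#' @param duration Surgery duration draw (minutes): normal with `mean`,
#'   `sd`, truncated to `[min, max]`.
#' @param baseline Anesthetized baseline vitals: means and SDs of heart rate
#'   (beats/min), systolic pressure (mmHg) and perfusion index (%) across
#'   patients.
#' @param gains Change in each vital per unit of nociceptive drive: `hr`
#'   (beats/min), `sbp` (mmHg), `pi` (% decrease). One drive unit therefore
#'   moves the stimulus term by `0.01*hr + 0.02*sbp + 0.17*pi`.
#' @param timeline Event placement: `t1` (loss of consciousness), `t2`
#'   (tracheal intubation), the window for surgery start (`t4_min`,
#'   `t4_max`), the T3-to-T4 gap window (`t3_gap_min`, `t3_gap_max`), and
#'   the emergence delay window to eye opening (`t6_min`, `t6_max`).
#' @param stimulus Nociceptive drive profile: `awake_drive` (pre-induction
#'   level), `surgical_drive` mean and between-patient SD (sustained
#'   pneumoperitoneum/dissection level), event pulse magnitudes and decay
#'   constants (minutes) for intubation, incision and wound closure,
#'   `pneumo_onset_lag` and `pneumo_rise_tau` (minutes), and
#'   `emergence_drive` (post-surgery level).
#' @param noise Mean-reverting (AR(1)/OU) fluctuation of the drive:
#'   stationary `sd` (drive units) and `corr_time` (minutes).
#' @param controller Closed-loop NR-guided analgesia emulation: `enabled`
#'   (set `FALSE` to run both arms without guidance, e.g. for null
#'   experiments), `threshold` (trigger level, default 0.85),
#'   `baseline_effect` (prophylactic drive
#'   reduction while NR guidance is active, emulating the deeper continuous
#'   analgesia of the guided arm), `effect_gain` (additional drive units
#'   subtracted at full reactive effect), `effect_lag` / `decay_lag`
#'   (first-order rise and decay times, minutes), `effect_max`,
#'   `persistence` (minutes of sustained exceedance before the secondary,
#'   landiolol-like stage engages), `secondary_gain`, `secondary_lag`,
#'   `secondary_decay`, and `gain_sd` (between-patient SD of the
#'   multiplicative titration-vigour factor applied to all three effects).
#' @param invasive_frac Named fractions of patients on invasive (every
#'   minute) pressure monitoring per arm; the rest are cuff-measured every
#'   5 minutes.
#' @param outcome Outcome models given per-patient mean NR: CRP linear model
#'   (`crp_intercept`, `crp_slope` per unit mean NR, `crp_sd`, mg/dL,
#'   truncated at 0), complication logit-linear model (`comp_intercept`,
#'   `comp_slope`), conditional grade-III share per arm (`grade3_share`),
#'   and the POD-1 pain score model (`nrs_intercept`, `nrs_slope`,
#'   `nrs_sd`; latent value rounded and clamped to 0--10).
#' @return An object of class `sim_config` (validated nested list).
#' @export
sim_config <- function(n_per_arm = 52,
                       seed = 1,
                       duration = list(mean = 230, sd = 45,
                                       min = 120, max = 340),
                       baseline = list(hr_mean = 62, hr_sd = 6,
                                       sbp_mean = 105, sbp_sd = 8,
                                       pi_mean = 5.0, pi_sd = 0.8),
                       gains = list(hr = 8, sbp = 15, pi = 1.5),
                       timeline = list(t1 = 3, t2 = 5,
                                       t4_min = 13, t4_max = 18,
                                       t3_gap_min = 1, t3_gap_max = 5,
                                       t6_min = 5, t6_max = 10),
                       stimulus = list(awake_drive = 2.1,
                                       surgical_drive = 0.675,
                                       surgical_drive_sd = 0.22,
                                       intubation_mag = 0.9,
                                       intubation_tau = 3,
                                       incision_mag = 0.8, incision_tau = 4,
                                       pneumo_onset_lag = 2,
                                       pneumo_rise_tau = 3,
                                       closure_mag = 0.4, closure_tau = 5,
                                       closure_before_end = 8,
                                       emergence_drive = 1.3),
                       noise = list(sd = 0.40, corr_time = 8),
                       controller = list(enabled = TRUE,
                                         threshold = 0.85,
                                         baseline_effect = 0.26,
                                         effect_gain = 0.95,
                                         effect_lag = 3, decay_lag = 120,
                                         effect_max = 1,
                                         persistence = 8,
                                         secondary_gain = 0.35,
                                         secondary_lag = 3,
                                         secondary_decay = 15,
                                         gain_sd = 0.62),
                       invasive_frac = c(control = 0.25, nr_guided = 0.21),
                       outcome = list(crp_intercept = -12.81,
                                      crp_slope = 20.27,
                                      crp_sd = 2.35,
                                      comp_intercept = -34.84,
                                      comp_slope = 42.06,
                                      grade3_share = c(control = 0.30,
                                                       nr_guided = 0.0),
                                      nrs_intercept = -28.3,
                                      nrs_slope = 40, nrs_sd = 1.2)) {
  cfg <- structure(list(n_per_arm = as.integer(n_per_arm),
                        seed = as.integer(seed),
                        duration = duration, baseline = baseline,
                        gains = gains, timeline = timeline,
                        stimulus = stimulus, noise = noise,
                        controller = controller,
                        invasive_frac = invasive_frac,
                        outcome = outcome),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, msg) if (!ok) bad <<- c(bad, msg)
  chk(cfg$n_per_arm >= 1, "n_per_arm must be >= 1")
  chk(cfg$duration$min <= cfg$duration$max && cfg$duration$sd >= 0,
      "duration: need sd >= 0 and min <= max")
  sds <- c(cfg$baseline$hr_sd, cfg$baseline$sbp_sd, cfg$baseline$pi_sd,
           cfg$stimulus$surgical_drive_sd, cfg$noise$sd, cfg$outcome$crp_sd,
           cfg$outcome$nrs_sd)
  chk(all(sds >= 0), "all SDs must be >= 0")
  chk(cfg$controller$threshold > 0 && cfg$controller$threshold < 1,
      "controller threshold must be in (0, 1)")
  chk(all(unlist(cfg$gains) >= 0), "gains must be >= 0")
  chk(all(cfg$invasive_frac >= 0 & cfg$invasive_frac <= 1),
      "invasive_frac must be in [0, 1]")
  chk(all(c("control", "nr_guided") %in% names(cfg$invasive_frac)),
      "invasive_frac must name both arms")
  chk(all(cfg$outcome$grade3_share >= 0 & cfg$outcome$grade3_share <= 1),
      "grade3_share must be in [0, 1]")
  with(cfg$timeline,
       chk(t1 < t2 && t2 < t4_min && t4_min <= t4_max &&
           t3_gap_min >= 1 && t3_gap_min <= t3_gap_max &&
           t4_min - t3_gap_max > t2,
           "timeline: need t1 < t2 < T3 < T4 windows in order"))
  if (length(bad)) {
    stop("invalid sim_config:\n  ", paste(bad, collapse = "\n  "))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  n_per_arm:", x$n_per_arm, " seed:", x$seed, "\n")
  cat(sprintf("  duration: %g +/- %g min (truncated %g-%g)\n",
              x$duration$mean, x$duration$sd, x$duration$min, x$duration$max))
  cat(sprintf("  controller: threshold %.2f, gain %.2f, lag %g min\n",
              x$controller$threshold, x$controller$effect_gain,
              x$controller$effect_lag))
  invisible(x)
}

#' Read a simulator configuration from YAML or JSON
#'
#' The file mirrors [sim_config()] field-for-field; fields not present keep
#' their defaults. Format is chosen by extension (`.yaml`/`.yml` requires
#' the yaml package, anything else is parsed as JSON).
#'
#' @param file Path to the config file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(file) {
  ext <- tolower(tools::file_ext(file))
  lst <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  defaults <- formals(sim_config)
  known <- names(defaults)
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(names(lst), function(nm) {
    val <- lst[[nm]]
    def <- eval(defaults[[nm]])
    if (is.list(def)) {
      bad <- setdiff(names(val), names(def))
      if (length(bad)) stop("unknown field(s) in ", nm, ": ",
                            paste(bad, collapse = ", "))
      def[names(val)] <- val
      def
    } else if (!is.null(names(def))) {
      def[names(val)] <- unlist(val)
      def
    } else {
      val
    }
  })
  names(args) <- names(lst)
  do.call(sim_config, args)
}
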