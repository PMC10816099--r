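#' Hemodynamic stimulus term of the nociceptive response index
#'
#' The stimulus term summarises the sympathetic signature of nociception in
#' three routinely monitored variables: heart rate and systolic pressure rise
#' with noxious stimulation while the plethysmographic perfusion index falls
#' with sympathetic vasoconstriction. The weights were fitted upstream to
#' discriminate surgical procedures of graded invasiveness and are fixed
#' constants of the index:
#'
#' \deqn{S = 0.01\,HR + 0.02\,SBP - 0.17\,PI}
#'
#' Perfusion index is on the usual pulse-oximeter percent scale (roughly
#' 0.2--20); the -0.17 weight is only meaningful on that scale.
#'
#' @param hr Heart rate, beats/min (> 0).
#' @param sbp Systolic blood pressure, mmHg (> 0).
#' @param pi Perfusion index, percent (>= 0).
#' @return The dimensionless stimulus term, vectorized over inputs.
#' @seealso [compute_nr()] for the logistic transform to the NR index.
#' @examples
#' compute_stimulus(hr = 70, sbp = 120, pi = 2.0)  # 2.76
#' @export
compute_stimulus <- function(hr, sbp, pi) {
  if (any(!is.finite(hr)) || any(!is.finite(sbp)) || any(!is.finite(pi))) {
    stop("incomplete sample: hr, sbp and pi must all be present and finite")
  }
  if (any(hr <= 0) || any(sbp <= 0)) stop("hr and sbp must be > 0")
  if (any(pi < 0)) stop("pi must be >= 0")
  0.01 * hr + 0.02 * sbp - 0.17 * pi
}

#' Nociceptive response (NR) index from the stimulus term
#'
#' Maps the stimulus term S to the NR index through the logistic response
#' curve \eqn{NR = 2/(1 + e^{-S}) - 1}, the solution of a logistic
#' differential equation in which the physiological response saturates under
#' feedback regulation (descending pain inhibition, baroreflex). The raw
#' transform lies in (-1, 1); because the index is defined on \[0, 1\],
#' negative values (possible under very high perfusion index, i.e. profound
#' vasodilation) are clamped to 0. The unclamped stimulus term is kept
#' alongside the index by [nr_from_vitals()] so no information is lost.
#'
#' @param s_value Stimulus term from [compute_stimulus()]; finite numeric.
#' @return NR index in \[0, 1\], vectorized.
#' @examples
#' compute_nr(0)      # 0: logistic midpoint
#' compute_nr(2.76)   # ~0.881
#' compute_nr(-1.8)   # clamped to 0
#' @export
compute_nr <- function(s_value) {
  if (any(!is.finite(s_value))) stop("s_value must be finite")
  pmax(2 / (1 + exp(-s_value)) - 1, 0)
}

#' Per-minute NR trace from a vital-sign series
#'
#' Computes the NR index on every minute of the grid, applying the anesthesia
#' record sampling conventions: the index is emitted from the first minute at
#' which all three signals have been observed, and on minutes without a fresh
#' systolic pressure (the 5-minute cuff cadence of non-invasive monitoring)
#' the most recent prior value is carried forward and flagged. There is no
#' backward fill and no interpolation; the index is undefined (not emitted)
#' before the first pressure observation.
#'
#' @param series A [vital_series].
#' @param threshold NR exceedance threshold used downstream; stored as an
#'   attribute for audit. Default 0.85, the guidance level of NR-guided care.
#' @return Data frame of class `nr_trace` with columns `t`, `s_value`, `nr`,
#'   `sbp_carried` (logical).
#' @examples
#' vs <- vital_series("p1",
#'   data.frame(t = 0:5, hr = 70, sbp = c(120, NA, NA, NA, NA, 140), pi = 2))
#' nr_from_vitals(vs)
#' @export
nr_from_vitals <- function(series, threshold = 0.85) {
  stopifnot(inherits(series, "vital_series"))
  s <- series$samples
  if (!nrow(s)) stop("empty series")
  if (any(diff(s$t) != 1L)) stop("non-contiguous grid: gaps > 1 min in samples")
  if (all(is.na(s$sbp))) stop("no SBP ever observed")

  first_sbp <- match(FALSE, is.na(s$sbp))
  keep <- seq(first_sbp, nrow(s))
  s <- s[keep, ]
  if (any(is.na(s$hr)) || any(is.na(s$pi))) {
    stop("incomplete sample: hr and pi must be observed on every minute ",
         "from the first SBP observation onward")
  }
  # last-observation-carried-forward for SBP only
  obs <- !is.na(s$sbp)
  idx <- cumsum(obs)                 # index of latest observation at each t
  sbp_f <- s$sbp[obs][idx]
  out <- data.frame(t = s$t,
                    s_value = compute_stimulus(s$hr, sbp_f, s$pi),
                    nr = NA_real_,
                    sbp_carried = !obs)
  out$nr <- compute_nr(out$s_value)
  attr(out, "patient_id") <- series$patient_id
  attr(out, "threshold") <- threshold
  class(out) <- c("nr_trace", "data.frame")
  out
}

#' Per-patient intraoperative NR summary
#'
#' Summarises an NR trace over the closed surgical window
#' \[`surgery_start`, `surgery_end`\]: highest, unweighted mean and lowest
#' per-minute NR, the fraction of surgical minutes at or above the exceedance
#' threshold, and the NR value at each annotated timepoint T0--T6. Optional
#' hypotension flags are derived from an externally supplied mean blood
#' pressure trace (MBP is not derivable from systolic pressure alone).
#'
#' @param points An `nr_trace` from [nr_from_vitals()].
#' @param events Named integer vector of event minutes; must contain
#'   `surgery_start` and `surgery_end`.
#' @param threshold Exceedance threshold; minutes with `NR >= threshold`
#'   count as exceedance (the guidance being to hold NR *below* 0.85).
#' @param mbp Optional numeric vector of per-minute mean blood pressure
#'   (mmHg) aligned with `points$t`, used only for the `< 55` / `< 65` mmHg
#'   hypotension flags.
#' @param patient_id Patient identifier; defaults to the trace attribute.
#' @return An object of class `nr_summary`: a list with elements
#'   `patient_id`, `highest_nr`, `mean_nr`, `lowest_nr`,
#'   `frac_above_threshold`, `timepoint_nr` (named numeric, absent
#'   timepoints dropped), `lowest_mbp_lt55`, `lowest_mbp_lt65`.
#' @export
summarize_nr <- function(points, events, threshold = 0.85, mbp = NULL,
                         patient_id = attr(points, "patient_id")) {
  stopifnot(is.data.frame(points), all(c("t", "nr") %in% names(points)))
  if (!all(c("surgery_start", "surgery_end") %in% names(events))) {
    stop("events must annotate surgery_start and surgery_end")
  }
  w0 <- as.integer(events[["surgery_start"]])
  w1 <- as.integer(events[["surgery_end"]])
  if (w0 > w1) stop("surgery_start must be <= surgery_end")
  in_win <- points$t >= w0 & points$t <= w1
  if (!any(points$t == w0) || !any(points$t == w1)) {
    stop("surgical window [", w0, ", ", w1, "] not covered by NR points")
  }
  nr <- points$nr[in_win]
  flags <- c(lowest_mbp_lt55 = NA, lowest_mbp_lt65 = NA)
  if (!is.null(mbp)) {
    stopifnot(length(mbp) == nrow(points))
    m <- min(mbp[in_win], na.rm = TRUE)
    flags <- c(lowest_mbp_lt55 = m < 55, lowest_mbp_lt65 = m < 65)
  }
  out <- list(patient_id = patient_id %||% NA_character_,
              highest_nr = max(nr),
              mean_nr = mean(nr),
              lowest_nr = min(nr),
              frac_above_threshold = mean(nr >= threshold),
              timepoint_nr = extract_timepoints(points, events),
              lowest_mbp_lt55 = flags[["lowest_mbp_lt55"]],
              lowest_mbp_lt65 = flags[["lowest_mbp_lt65"]])
  class(out) <- "nr_summary"
  out
}

#' @export
print.nr_summary <- function(x, ...) {
  cat("<nr_summary>", x$patient_id, "\n")
  cat(sprintf("  NR highest/mean/lowest: %.3f / %.3f / %.3f\n",
              x$highest_nr, x$mean_nr, x$lowest_nr))
  cat(sprintf("  minutes at or above threshold: %.1f%%\n",
              100 * x$frac_above_threshold))
  if (length(x$timepoint_nr)) {
    cat("  timepoints:", paste(sprintf("%s=%.3f", names(x$timepoint_nr),
                                       x$timepoint_nr), collapse = " "), "\n")
  }
  invisible(x)
}

#' NR values at annotated perioperative timepoints
#'
#' Reads the NR trace at the annotated minute of each timepoint T0 (awake,
#' before induction) through T6 (eye opening). T0 typically precedes the
#' surgical window. Timepoints not annotated, or annotated at minutes before
#' the trace starts, are reported as absent rather than as errors.
#'
#' @param points An `nr_trace`.
#' @param events Named integer vector of event minutes.
#' @param which Timepoint names to extract; defaults to T0--T6.
#' @return Named numeric vector of NR values for the annotated timepoints.
#' @export
extract_timepoints <- function(points, events,
                               which = paste0("T", 0:6)) {
  present <- intersect(which, names(events))
  out <- vapply(present, function(nm) {
    i <- match(as.integer(events[[nm]]), points$t)
    if (is.na(i)) NA_real_ else points$nr[i]
  }, numeric(1))
  out[!is.na(out)]
}

#' Write an NR trace to CSV
#'
#' @param trace An `nr_trace`, or list of them.
#' @param file Output path. Columns: `patient_id, t_min, s_value, nr,
#'   sbp_carried`.
#' @return Invisibly, the data frame written.
#' @export
write_nr_trace <- function(trace, file) {
  if (inherits(trace, "nr_trace")) trace <- list(trace)
  d <- do.call(rbind, lapply(trace, function(tr) {
    data.frame(patient_id = attr(tr, "patient_id") %||% NA_character_,
               t_min = tr$t, s_value = tr$s_value, nr = tr$nr,
               sbp_carried = tr$sbp_carried)
  }))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
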