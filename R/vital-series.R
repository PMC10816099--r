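#' Per-minute intraoperative vital-sign series for one patient
#'
#' Container for a single patient's per-minute heart rate, systolic blood
#' pressure and perfusion index trace, together with named event annotations
#' (induction timepoints T0--T6, surgery start/end) and the pre-anesthesia
#' systolic pressure reference.
#'
#' The time axis is a strictly increasing integer minute grid. Systolic
#' pressure may be missing (`NA`) on minutes without a cuff measurement;
#' heart rate and perfusion index are expected every minute once monitoring
#' has started. Input recorded at finer resolution must be binned to minutes
#' (mean within minute) before construction.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param samples Data frame with columns `t` (integer minutes), `hr`
#'   (beats/min), `sbp` (mmHg, `NA` on non-measurement minutes), `pi`
#'   (perfusion index, percent) and optionally `sbp_source`
#'   (`"invasive"` or `"noninvasive"`).
#' @param events Named integer vector mapping event names (`T0` ... `T6`,
#'   `surgery_start`, `surgery_end`) to minute indices on the grid.
#' @param pre_anesthesia_sbp Optional pre-anesthesia systolic pressure
#'   reference (mmHg), used by the simulator's pressure-band convention.
#'
#' @return An object of class `vital_series`.
#' @examples
#' vs <- vital_series("p1",
#'   data.frame(t = 0:5, hr = 70, sbp = c(120, NA, NA, NA, NA, 140), pi = 2),
#'   events = c(surgery_start = 0, surgery_end = 5))
#' vs
#' @export
vital_series <- function(patient_id, samples, events = integer(),
                         pre_anesthesia_sbp = NA_real_) {
  stopifnot(is.data.frame(samples),
            all(c("t", "hr", "sbp", "pi") %in% names(samples)))
  if (is.null(samples$sbp_source)) {
    samples$sbp_source <- ifelse(is.na(samples$sbp), NA_character_, "noninvasive")
  }
  samples <- samples[order(samples$t), c("t", "hr", "sbp", "pi", "sbp_source")]
  samples$t <- as.integer(samples$t)
  events <- if (length(events)) {
    stats::setNames(as.integer(events), names(events))
  } else {
    integer()
  }
  obj <- structure(
    list(patient_id = as.character(patient_id),
         samples = samples,
         events = events,
         pre_anesthesia_sbp = as.numeric(pre_anesthesia_sbp)),
    class = "vital_series")
  validate_vital_series(obj)
  obj
}

validate_vital_series <- function(x) {
  s <- x$samples
  if (anyDuplicated(s$t)) stop("duplicate minute indices in samples")
  if (any(diff(s$t) <= 0)) stop("sample times must be strictly increasing")
  if (any(s$t < 0)) stop("minute indices must be >= 0")
  if (any(!is.na(s$hr) & s$hr <= 0)) stop("hr must be > 0 when present")
  if (any(!is.na(s$sbp) & s$sbp <= 0)) stop("sbp must be > 0 when present")
  if (any(!is.na(s$pi) & s$pi < 0)) stop("pi must be >= 0")
  ev <- x$events
  if (length(ev)) {
    if (!all(ev %in% s$t)) {
      stop("event minute(s) not on the sample grid: ",
           paste(names(ev)[!ev %in% s$t], collapse = ", "))
    }
    if (all(c("surgery_start", "surgery_end") %in% names(ev)) &&
        ev[["surgery_start"]] > ev[["surgery_end"]]) {
      stop("surgery_start must be <= surgery_end")
    }
  }
  invisible(x)
}

#' @export
print.vital_series <- function(x, ...) {
  s <- x$samples
  cat("<vital_series> patient", x$patient_id, "\n")
  cat("  minutes:", nrow(s), sprintf("(t = %d..%d)", min(s$t), max(s$t)), "\n")
  cat("  sbp observed on", sum(!is.na(s$sbp)), "minutes\n")
  if (length(x$events)) {
    cat("  events:", paste(sprintf("%s=%d", names(x$events), x$events),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Read per-minute vitals and event annotations from CSV
#'
#' `read_vitals_csv()` reads a long-format vitals table (columns
#' `patient_id, t_min, hr, sbp, pi, sbp_source`; empty cells are missing) and
#' an optional events table (`patient_id, event_name, t_min`) and returns one
#' [vital_series] per patient.
#'
#' @param vitals_file Path to the vitals CSV.
#' @param events_file Optional path to the events CSV.
#' @return Named list of [vital_series], one element per patient.
#' @export
read_vitals_csv <- function(vitals_file, events_file = NULL) {
  v <- utils::read.csv(vitals_file, stringsAsFactors = FALSE)
  need <- c("patient_id", "t_min", "hr", "sbp", "pi")
  if (!all(need %in% names(v))) {
    stop("vitals CSV must have columns: ", paste(need, collapse = ", "))
  }
  ev <- NULL
  if (!is.null(events_file)) {
    ev <- utils::read.csv(events_file, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "event_name", "t_min") %in% names(ev))) {
      stop("events CSV must have columns: patient_id, event_name, t_min")
    }
  }
  out <- lapply(split(v, v$patient_id), function(d) {
    samples <- data.frame(t = d$t_min, hr = d$hr, sbp = d$sbp, pi = d$pi,
                          sbp_source = if (is.null(d$sbp_source)) NA_character_
                                       else d$sbp_source)
    events <- integer()
    if (!is.null(ev)) {
      e <- ev[ev$patient_id == d$patient_id[1], ]
      events <- stats::setNames(as.integer(e$t_min), e$event_name)
    }
    vital_series(d$patient_id[1], samples, events)
  })
  out[order(names(out))]
}

#' Write one or more vital series back to long-format CSV
#'
#' @param series A [vital_series] or list of them.
#' @param vitals_file Output path for the vitals CSV.
#' @param events_file Optional output path for the events CSV.
#' @return Invisibly, the vitals data frame written.
#' @export
write_vitals_csv <- function(series, vitals_file, events_file = NULL) {
  if (inherits(series, "vital_series")) series <- list(series)
  vit <- do.call(rbind, lapply(series, function(vs) {
    data.frame(patient_id = vs$patient_id, t_min = vs$samples$t,
               hr = vs$samples$hr, sbp = vs$samples$sbp, pi = vs$samples$pi,
               sbp_source = vs$samples$sbp_source)
  }))
  utils::write.csv(vit, vitals_file, row.names = FALSE, na = "")
  if (!is.null(events_file)) {
    evd <- do.call(rbind, lapply(series, function(vs) {
      if (!length(vs$events)) return(NULL)
      data.frame(patient_id = vs$patient_id, event_name = names(vs$events),
                 t_min = unname(vs$events))
    }))
    utils::write.csv(evd, events_file, row.names = FALSE, na = "")
  }
  invisible(vit)
}
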