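fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

fmt_mean_ci <- function(x, level = 0.95) {
  ci <- stats::t.test(x, conf.level = level)$conf.int
  sprintf("%.2f [%.2f-%.2f]", mean(x), ci[1], ci[2])
}

fmt_count_ci <- function(k, n) {
  w <- wilson_ci(k, n)
  sprintf("%d (%.1f%% [%.1f-%.1f])", k, 100 * k / n, 100 * w$lo, 100 * w$hi)
}

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 2)
  sprintf("%g (%g-%g)", q[2], q[1], q[3])
}

# chi-square on an event-count contrast; degenerate margins (no events, or
# events in everyone) are reported as not estimable rather than as errors
count_test <- function(k1, n1, k2, n2, endpoint, alpha_adjusted = 0.05) {
  tot <- k1 + k2
  if (tot == 0 || tot == n1 + n2) {
    return(comparison_result(endpoint, "chi2_not_estimable", NA_real_, 1,
                             alpha_adjusted))
  }
  pearson_chi2_2x2(k1, n1 - k1, k2, n2 - k2, endpoint = endpoint,
                   alpha_adjusted = alpha_adjusted)
}

report_row <- function(endpoint, control, nr_guided, estimate = NA,
                       lo = NA, hi = NA, p_value = NA, alpha = NA,
                       method = "", co_primary = FALSE) {
  data.frame(endpoint = endpoint, control = control, nr_guided = nr_guided,
             estimate = estimate, lo = lo, hi = hi, p_value = p_value,
             alpha = alpha, method = method, co_primary = co_primary,
             stringsAsFactors = FALSE)
}

#' Analyze a simulated (or imported) trial dataset
#'
#' Produces the three analysis tables of a two-arm NR-guided trial:
#' a baseline/monitoring balance table (standardized mean differences), an
#' intraoperative NR table (unpaired t-tests on highest/mean/lowest NR,
#' exceedance fraction by Mann-Whitney), and the outcome table (CRP by
#' unpaired t at the co-primary Bonferroni threshold 0.025, complication
#' rates with Wilson CIs, uncorrected chi-square and Katz relative risk at
#' 0.025, grade-specific rows at 0.05, pain scores by Mann-Whitney), plus
#' the T0--T6 timepoint comparisons at the 0.05/6 threshold.
#'
#' @param dataset A `trial_dataset` from [simulate_trial()]; may be omitted
#'   when `summaries` and `outcomes` are given directly (e.g. read back from
#'   the CSVs written by [write_trial_csv()]).
#' @param summaries,outcomes Per-patient tables in the format of
#'   [trial_summaries()] and [trial_outcomes()].
#' @return A named list of data frames (`balance`, `intraop`, `outcomes`,
#'   `timepoints`), each with a `method` column naming the estimator.
#' @export
analyze_trial <- function(dataset, summaries = trial_summaries(dataset),
                          outcomes = trial_outcomes(dataset)) {
  summ <- summaries
  outc <- outcomes
  stopifnot(identical(sort(summ$patient_id), sort(outc$patient_id)))
  sc <- summ[summ$arm == "control", ]
  sn <- summ[summ$arm == "nr_guided", ]
  oc <- outc[outc$arm == "control", ]
  on_ <- outc[outc$arm == "nr_guided", ]
  nc <- nrow(sc); nn <- nrow(sn)

  a_co <- bonferroni_threshold(0.05, 2)
  a_tp <- bonferroni_threshold(0.05, 6)

  balance <- rbind(
    report_row("duration_min",
               sprintf("%.0f +/- %.0f", mean(sc$duration_min), stats::sd(sc$duration_min)),
               sprintf("%.0f +/- %.0f", mean(sn$duration_min), stats::sd(sn$duration_min)),
               estimate = smd_continuous(mean(sc$duration_min), stats::sd(sc$duration_min),
                                         mean(sn$duration_min), stats::sd(sn$duration_min)),
               method = "smd_continuous"),
    report_row("invasive_monitoring",
               fmt_count_ci(sum(sc$invasive), nc),
               fmt_count_ci(sum(sn$invasive), nn),
               estimate = smd_binary(mean(sc$invasive), mean(sn$invasive)),
               method = "smd_binary"),
    report_row("nr_T0",
               sprintf("%.3f +/- %.3f", mean(sc$T0), stats::sd(sc$T0)),
               sprintf("%.3f +/- %.3f", mean(sn$T0), stats::sd(sn$T0)),
               estimate = smd_continuous(mean(sc$T0), stats::sd(sc$T0),
                                         mean(sn$T0), stats::sd(sn$T0)),
               method = "smd_continuous"))

  t_or_na <- function(x, y, endpoint, alpha = 0.05) {
    r <- unpaired_t(x, y, endpoint = endpoint, alpha_adjusted = alpha)
    report_row(endpoint,
               sprintf("%.3f +/- %.3f", mean(x), stats::sd(x)),
               sprintf("%.3f +/- %.3f", mean(y), stats::sd(y)),
               estimate = r$estimate, p_value = r$p_value, alpha = alpha,
               method = r$method)
  }
  mw_land <- count_test(sum(sc$landiolol), nc, sum(sn$landiolol), nn,
                        endpoint = "landiolol")
  fr <- mann_whitney_u(sc$frac_above_threshold, sn$frac_above_threshold,
                       endpoint = "frac_nr_ge_threshold")
  intraop <- rbind(
    t_or_na(sc$highest_nr, sn$highest_nr, "highest_nr"),
    t_or_na(sc$mean_nr, sn$mean_nr, "mean_nr"),
    t_or_na(sc$lowest_nr, sn$lowest_nr, "lowest_nr"),
    report_row("frac_nr_ge_threshold",
               fmt_median_iqr(sc$frac_above_threshold),
               fmt_median_iqr(sn$frac_above_threshold),
               p_value = fr$p_value, alpha = 0.05, method = fr$method),
    report_row("landiolol_used",
               sprintf("%d (%.1f%%)", sum(sc$landiolol), 100 * mean(sc$landiolol)),
               sprintf("%d (%.1f%%)", sum(sn$landiolol), 100 * mean(sn$landiolol)),
               p_value = mw_land$p_value, alpha = 0.05, method = mw_land$method))

  kc <- sum(oc$complication); kn <- sum(on_$complication)
  crp_t <- unpaired_t(oc$crp_pod1, on_$crp_pod1, endpoint = "crp_pod1",
                      alpha_adjusted = a_co)
  comp_chi <- pearson_chi2_2x2(kc, nc - kc, kn, nn - kn,
                               endpoint = "complication",
                               alpha_adjusted = a_co)
  rr <- risk_ratio(kn, nn, kc, nc)
  g2c <- sum(oc$clavien_dindo == "II"); g2n <- sum(on_$clavien_dindo == "II")
  g3c <- sum(oc$clavien_dindo == "III"); g3n <- sum(on_$clavien_dindo == "III")
  g2_chi <- count_test(g2c, nc, g2n, nn, endpoint = "grade_II")
  g3_chi <- count_test(g3c, nc, g3n, nn, endpoint = "grade_III")
  nrs <- mann_whitney_u(oc$nrs_pod1, on_$nrs_pod1, endpoint = "nrs_pod1")
  outcomes <- rbind(
    report_row("crp_pod1", fmt_mean_ci(oc$crp_pod1), fmt_mean_ci(on_$crp_pod1),
               estimate = crp_t$estimate, p_value = crp_t$p_value,
               alpha = a_co, method = crp_t$method, co_primary = TRUE),
    report_row("complication", fmt_count_ci(kc, nc), fmt_count_ci(kn, nn),
               estimate = rr$rr, lo = rr$lo, hi = rr$hi,
               p_value = comp_chi$p_value, alpha = a_co,
               method = "pearson_chi2_uncorrected+katz", co_primary = TRUE),
    report_row("grade_II", fmt_count_ci(g2c, nc), fmt_count_ci(g2n, nn),
               p_value = g2_chi$p_value, alpha = 0.05, method = g2_chi$method),
    report_row("grade_III", fmt_count_ci(g3c, nc), fmt_count_ci(g3n, nn),
               p_value = g3_chi$p_value, alpha = 0.05, method = g3_chi$method),
    report_row("nrs_pod1", fmt_median_iqr(oc$nrs_pod1),
               fmt_median_iqr(on_$nrs_pod1),
               p_value = nrs$p_value, alpha = 0.05, method = nrs$method))

  timepoints <- do.call(rbind, lapply(paste0("T", 0:6), function(tp) {
    x <- sc[[tp]]; y <- sn[[tp]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    t_or_na(x, y, paste0("nr_", tp), alpha = a_tp)
  }))

  list(balance = balance, intraop = intraop, outcomes = outcomes,
       timepoints = timepoints)
}

#' Run the full trial pipeline: simulate, compute NR, summarise, analyze
#'
#' Simulates a trial from `config`, writes the dataset CSVs (vitals, events,
#' NR traces, outcomes), the four analysis reports and a JSON run manifest
#' under `out_dir`, and returns the manifest. Re-running with the same
#' config yields byte-identical analysis CSVs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return An object of class `run_manifest` (invisibly also written as
#'   `manifest.json`): config hash, seed, generator version, file list.
#' @export
run_trial <- function(config = sim_config(), out_dir = tempfile("nociguard_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- simulate_trial(config)
  files <- write_trial_csv(dataset, out_dir)
  reports <- analyze_trial(dataset)
  for (nm in names(reports)) {
    f <- file.path(out_dir, paste0("report_", nm, ".csv"))
    utils::write.csv(reports[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- structure(
    list(config_hash = fnv1a(as.character(cfg_json)),
         seed = config$seed,
         generator = dataset$provenance$generator,
         n_patients = length(dataset$patients),
         files = basename(unname(files)),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "config", x$config_hash, "\n")
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  invisible(x)
}

#' Simulation-based power (and type-I error) experiment
#'
#' Estimates the empirical power of the trial's analysis for an endpoint by
#' repeated simulation at each sample size on a grid, using the same test
#' functions as [analyze_trial()] (uncorrected Pearson chi-square for the
#' complication endpoint, Student's unpaired t for the CRP endpoint). With
#' equal generating parameters in the two arms the rejection fraction
#' estimates the type-I error instead.
#'
#' Endpoint generation is at the arm-level design parameters (event rates
#' for `complication`, means/SDs for `crp`), which is the simulation twin of
#' the analytic sample-size formulas; the full per-minute simulator is not
#' re-run inside each replicate.
#'
#' @param endpoint `"complication"` or `"crp"`.
#' @param n_grid Integer vector of per-arm sample sizes.
#' @param replicates Simulated trials per grid point (>= 100 recommended).
#' @param rates Named generating event probabilities
#'   (complication endpoint), default `c(control = 0.36, nr_guided = 0.12)`,
#'   the design assumptions of the two-proportion sample-size calculation.
#' @param means,sds Generating means and SDs per arm (crp endpoint),
#'   default `c(control = 3.9, nr_guided = 2.6)` and `c(2.34, 2.37)`.
#' @param alpha Significance threshold applied to each replicate.
#' @param seed Seed for the experiment.
#' @return Data frame of class `power_result`: one row per `n` with
#'   `endpoint`, `n_per_arm`, `replicates`, `alpha`, `empirical_power`,
#'   `mc_se`.
#' @examples
#' power_experiment("complication", n_grid = 49, replicates = 200, seed = 1)
#' @export
power_experiment <- function(endpoint = c("complication", "crp"),
                             n_grid = c(30, 40, 49, 60),
                             replicates = 1000,
                             rates = c(control = 0.36, nr_guided = 0.12),
                             means = c(control = 3.9, nr_guided = 2.6),
                             sds = c(control = 2.34, nr_guided = 2.37),
                             alpha = 0.05, seed = 1) {
  endpoint <- match.arg(endpoint)
  set.seed(seed)
  res <- lapply(n_grid, function(n) {
    sig <- logical(replicates)
    for (r in seq_len(replicates)) {
      if (endpoint == "complication") {
        kc <- stats::rbinom(1, n, rates[["control"]])
        kn <- stats::rbinom(1, n, rates[["nr_guided"]])
        p <- if ((kc + kn) == 0 || (kc + kn) == 2 * n) 1 else {
          pearson_chi2_2x2(kc, n - kc, kn, n - kn)$p_value
        }
      } else {
        xc <- stats::rnorm(n, means[["control"]], sds[["control"]])
        xn <- stats::rnorm(n, means[["nr_guided"]], sds[["nr_guided"]])
        p <- unpaired_t(xc, xn)$p_value
      }
      sig[r] <- p < alpha
    }
    pw <- mean(sig)
    data.frame(endpoint = endpoint, n_per_arm = n, replicates = replicates,
               alpha = alpha, empirical_power = pw,
               mc_se = sqrt(pw * (1 - pw) / replicates))
  })
  out <- do.call(rbind, res)
  class(out) <- c("power_result", "data.frame")
  out
}
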