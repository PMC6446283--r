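# Pipeline orchestration: simulate -> quantify -> analyze as reproducible,
# configured, logged runs. Every run writes a manifest (resolved parameters
# and seeds) sufficient to re-execute it exactly.

#' Simulate a cohort and write it to disk
#'
#' Writes one NIfTI sodium volume per session (`<subject>_<visit>_na.nii.gz`),
#' the anatomical label volume (`labels.nii.gz`), the ground-truth
#' concentration table (`truth.csv`), the per-session parameters
#' (`sessions.csv`) and a YAML run manifest.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_subjects Number of subjects. Default 12.
#' @param ... Further arguments to [simulate_cohort()].
#' @return The in-memory `sodium_cohort`, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, n_subjects = 12, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(n_subjects = n_subjects, seed = seed, ...)
  message("simulated ", length(cohort$sessions), " sessions (seed ", seed, ")")
  for (key in names(cohort$sessions)) {
    s <- cohort$sessions[[key]]
    fn <- file.path(out_dir, sprintf("%s_%s_na.nii.gz",
                                     s$spec$subject, s$spec$visit))
    write_nifti(s$image, fn)
  }
  write_nifti(vol_as_numeric(cohort$cache$labels),
              file.path(out_dir, "labels.nii.gz"))
  tr <- cohort$truth
  tr$true_conc <- format(tr$true_conc, digits = 17, scientific = FALSE,
                         trim = TRUE)
  utils::write.csv(tr, file.path(out_dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sessions_table(cohort), file.path(out_dir, "sessions.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(step = "simulate", seed = seed, n_subjects = n_subjects,
                   n_sessions = length(cohort$sessions),
                   args = lapply(list(...), function(a)
                     if (is.atomic(a)) a else class(a)[1]))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(cohort)
}

vol_as_numeric <- function(v) volume(v$data * 1.0, v$spacing, v$origin)

sessions_table <- function(cohort) {
  do.call(rbind, lapply(cohort$sessions, function(s) {
    sp <- s$spec
    data.frame(subject = sp$subject, visit = sp$visit,
               gain = format(sp$gain, digits = 17, trim = TRUE),
               tx = sp$transform$translation[1],
               ty = sp$transform$translation[2],
               tz = sp$transform$translation[3],
               rx = sp$transform$rotation_deg[1],
               ry = sp$transform$rotation_deg[2],
               rz = sp$transform$rotation_deg[3],
               noise_sigma = sp$noise_sigma, noise_seed = sp$seed,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Quantify a simulated cohort into a measurement table
#'
#' Runs [measure_all()] and writes `measurements.csv` plus a manifest. Logs
#' the reference-tube signal level per session.
#'
#' @param cohort A `sodium_cohort` (from [run_simulate()] /
#'   [simulate_cohort()]).
#' @param out_dir Output directory.
#' @param landmarks Landmark table (default [default_landmarks()]).
#' @param ... Further arguments to [measure_all()] (readers, jitter_sd, ...).
#' @return The measurement data.frame, invisibly.
#' @export
run_quantify <- function(cohort, out_dir, landmarks = default_landmarks(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meas <- measure_all(cohort, landmarks = landmarks, ...)
  write_measurements(meas, file.path(out_dir, "measurements.csv"))
  manifest <- list(step = "quantify", n_measurements = nrow(meas),
                   n_landmarks = nrow(landmarks))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest_quantify.yaml"))
  message("wrote ", nrow(meas), " measurements")
  invisible(meas)
}

#' Analyze a measurement table
#'
#' Runs [summarize_cohort()] and writes the report CSVs (see
#' [write_report()]). Idempotent: identical inputs give byte-identical
#' outputs.
#'
#' @param measurements Measurement data.frame or path to a measurement CSV.
#' @param out_dir Output directory.
#' @param ... Further arguments to [summarize_cohort()].
#' @return The `repeatability_report`, invisibly.
#' @export
run_analyze <- function(measurements, out_dir, ...) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  report <- summarize_cohort(measurements, ...)
  write_report(report, out_dir)
  message("report written to ", out_dir)
  invisible(report)
}

#' Run the full pipeline
#'
#' simulate -> quantify -> analyze with a single master seed; all outputs
#' under `out_dir` (`images/`, `measurements.csv`, `report/`).
#'
#' @param out_dir Output directory.
#' @param seed Master seed driving every random draw.
#' @param n_subjects Number of subjects. Default 12.
#' @param sim_args List of extra arguments for [simulate_cohort()].
#' @param quant_args List of extra arguments for [measure_all()].
#' @param stats_args List of extra arguments for [summarize_cohort()].
#' @return The `repeatability_report`, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_subjects = 12,
                         sim_args = list(), quant_args = list(),
                         stats_args = list()) {
  cohort <- do.call(run_simulate,
                    c(list(out_dir = file.path(out_dir, "images"),
                           seed = seed, n_subjects = n_subjects), sim_args))
  meas <- do.call(run_quantify,
                  c(list(cohort = cohort, out_dir = out_dir), quant_args))
  do.call(run_analyze,
          c(list(measurements = meas, out_dir = file.path(out_dir, "report"),
                 seed = seed), stats_args))
}
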