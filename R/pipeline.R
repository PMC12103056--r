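#' Pipeline configuration
#'
#' Serializable run configuration tying the simulation and analysis
#' stages together. Every pipeline invocation writes its effective
#' configuration beside its outputs.
#'
#' @param seed master RNG seed.
#' @param n_per_group participants per group.
#' @param calibration_path calibration profile CSV (`NULL` = shipped
#'   default).
#' @param run_battery also run the adaptive battery per participant?
#' @param write_stimuli write a handful of example stimulus WAV files?
#' @param efa_factors named vector of per-group EFA factor counts.
#' @param output_dir where pipeline outputs go.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_per_group = 35,
                            calibration_path = NULL, run_battery = FALSE,
                            write_stimuli = FALSE,
                            efa_factors = c(MCI = 3, control = 4),
                            output_dir = "capsim_out") {
  if (!is.numeric(seed) || !is.numeric(n_per_group) || n_per_group < 2)
    stop("invalid pipeline config: seed must be numeric and n_per_group >= 2")
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         calibration_path = calibration_path, run_battery = run_battery,
         write_stimuli = write_stimuli, efa_factors = efa_factors,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

write_manifest <- function(config, dir, files) {
  manifest <- list(
    package = "capsim",
    version = as.character(utils::packageVersion("capsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
}

#' Simulate a cohort to disk
#'
#' Generates the calibrated cohort (optionally with the adaptive battery
#' run per participant), writes it as CSV along with a few example
#' stimulus WAVs and a JSON run manifest echoing the configuration and
#' seed.
#'
#' @param config a [pipeline_config()].
#' @return Path of the cohort CSV, invisibly.
#' @export
pipeline_simulate <- function(config = pipeline_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- if (is.null(config$calibration_path)) default_calibration()
             else default_calibration(config$calibration_path)
  cohort <- generate_cohort(config$n_per_group, profile, seed = config$seed)
  if (isTRUE(config$run_battery))
    cohort <- simulate_measured_battery(cohort, seed = config$seed + 1L)
  cohort_path <- file.path(config$output_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)
  files <- list(cohort = "cohort.csv")
  if (isTRUE(config$write_stimuli)) {
    s <- config$seed
    wavs <- list(
      tfs_target_500_hz = synth_tfs_interval(
        tfs_interval_spec(500, target = TRUE)),
      fm_depth25 = synth_fm_tone(25),
      gap_10ms = synth_gap_noise(10, seed = s),
      am_m05 = synth_am_noise(0.5, seed = s))
    for (nm in names(wavs)) {
      fn <- sprintf("%s_seed%d.wav", nm, s)
      write_wav(wavs[[nm]], file.path(config$output_dir, fn))
      files[[nm]] <- fn
    }
  }
  write_manifest(config, config$output_dir, files)
  invisible(cohort_path)
}

#' Analyze a cohort CSV to report files
#'
#' Validates the cohort schema, runs [run_full_analysis()] and writes the
#' JSON and Markdown reports plus a manifest.
#'
#' @param cohort_path cohort CSV written by [pipeline_simulate()].
#' @param config a [pipeline_config()] (its `efa_factors` and
#'   `output_dir` are used).
#' @return Path of the JSON report, invisibly.
#' @export
pipeline_analyze <- function(cohort_path, config = pipeline_config()) {
  cohort <- read_cohort(cohort_path)
  validate_cohort_schema(cohort)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- run_full_analysis(
    cohort, analysis_config(efa_factors = config$efa_factors))
  json_path <- file.path(config$output_dir, "report.json")
  md_path <- file.path(config$output_dir, "report.md")
  write_report(report, json_path, md_path)
  write_manifest(config, config$output_dir,
                 list(report_json = "report.json", report_md = "report.md"))
  invisible(json_path)
}

#' Print the power / sample-size table
#'
#' @param d effect size; @param alpha significance level;
#' @param power target power; @param tails 1 or 2;
#' @param dropout expected dropout proportion.
#' @return The computed sizes, invisibly.
#' @export
pipeline_power <- function(d = 0.8, alpha = 0.05, power = 0.90, tails = 1,
                           dropout = 0.25) {
  n <- power_n_per_group(d, alpha, power, tails)
  total <- 2L * n
  infl <- inflate_for_dropout(total, dropout)
  cat(sprintf("d = %g, alpha = %g, power = %g, %d-tailed\n",
              d, alpha, power, tails))
  cat(sprintf("n per group: %d\ntotal N: %d\nafter %.0f%% dropout: %d (%d per group)\n",
              n, total, 100 * dropout, infl, infl %/% 2L))
  invisible(list(n_per_group = n, total_n = total, inflated_n = infl))
}
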