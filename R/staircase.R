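#' Transformed up-down staircase configuration
#'
#' Rulebook for a transformed up-down (n-down-1-up) adaptive track. After
#' `n_down` consecutive correct responses the stimulus steps toward harder;
#' after any incorrect response it steps toward easier. A reversal is
#' recorded whenever the step direction flips; the track stops once
#' `n_reversals_stop` reversals have been logged and the threshold is the
#' (geometric or arithmetic) mean of the last `n_reversals_use` reversal
#' values.
#'
#' In multiplicative mode the step factors are applied directly
#' (`value * step_down_factor` toward harder, `value * step_up_factor`
#' toward easier), so e.g. a gap-detection track uses `step_down_factor =
#' 0.5`, `step_up_factor = 2`. In additive mode they are magnitudes added
#' or subtracted according to `harder_direction`.
#'
#' @param name identifier echoed into results.
#' @param n_down consecutive correct responses per harder step.
#' @param n_up incorrect responses per easier step (1 for all presets).
#' @param step_mode `"multiplicative"` or `"additive"`.
#' @param step_down_factor,step_up_factor step magnitudes (see Details).
#' @param initial_value starting stimulus value.
#' @param floor,ceiling bounds on the tracked value, in stimulus units.
#' @param harder_direction `"increase"` or `"decrease"`: whether harder
#'   raises or lowers the tracked value.
#' @param n_reversals_stop reversals required to terminate.
#' @param n_reversals_use trailing reversals entering the threshold.
#' @param aggregator `"geometric"` or `"arithmetic"` reversal mean.
#' @param report_db if `TRUE` the threshold is reported as
#'   `20 * log10(value)` dB (modulation-depth convention).
#' @param max_trials safety cap on trial count.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(name = "track",
                             n_down = 2, n_up = 1,
                             step_mode = c("multiplicative", "additive"),
                             step_down_factor, step_up_factor,
                             initial_value, floor, ceiling,
                             harder_direction = c("decrease", "increase"),
                             n_reversals_stop = 8, n_reversals_use = 6,
                             aggregator = c("geometric", "arithmetic"),
                             report_db = FALSE, max_trials = 400) {
  step_mode <- match.arg(step_mode)
  harder_direction <- match.arg(harder_direction)
  aggregator <- match.arg(aggregator)
  if (floor >= ceiling) stop("floor must be < ceiling")
  if (step_down_factor <= 0 || step_up_factor <= 0)
    stop("step factors must be positive")
  if (n_reversals_use > n_reversals_stop)
    stop("n_reversals_use must be <= n_reversals_stop")
  if (step_mode == "multiplicative") {
    if (floor <= 0)
      stop("multiplicative tracks require a positive floor")
    harder_raises <- step_down_factor > 1
    if (harder_raises != (harder_direction == "increase"))
      stop("step_down_factor must move the value toward harder_direction")
  }
  if (initial_value < floor || initial_value > ceiling)
    stop("initial_value must lie in [floor, ceiling]")
  structure(
    list(name = name, n_down = n_down, n_up = n_up, step_mode = step_mode,
         step_down_factor = step_down_factor,
         step_up_factor = step_up_factor,
         initial_value = initial_value, floor = floor, ceiling = ceiling,
         harder_direction = harder_direction,
         n_reversals_stop = n_reversals_stop,
         n_reversals_use = n_reversals_use,
         aggregator = aggregator, report_db = report_db,
         max_trials = max_trials),
    class = "staircase_config"
  )
}

#' The four battery staircase presets
#'
#' Returns the staircase configurations for the four adaptive
#' temporal-processing tests:
#' \describe{
#'   \item{tfs_af}{interaural-phase frequency track: 2-down-1-up, start
#'     200 Hz, factor 1.25 up to a 4000 Hz ceiling (harder = higher
#'     frequency), 8 reversals, geometric mean of the last 6.}
#'   \item{fmdl}{FM depth track: start 25 Hz, halve on two correct, double
#'     on one incorrect, 8 reversals, last 6.}
#'   \item{attr}{gap-duration track: start 10 ms, factor 0.5 down / 2 up,
#'     8 reversals, geometric mean of the last 6.}
#'   \item{mdt}{AM depth track: start m = 0.5, factor 1.25, 4 reversals,
#'     geometric mean of the last 2, reported as 20 log10(m) dB.}
#' }
#'
#' @return Named list of [staircase_config()] objects.
#' @export
battery_staircase_configs <- function() {
  list(
    tfs_af = staircase_config(
      name = "tfs_af", step_down_factor = 1.25, step_up_factor = 1 / 1.25,
      initial_value = 200, floor = 30, ceiling = 4000,
      harder_direction = "increase"),
    fmdl = staircase_config(
      name = "fmdl", step_down_factor = 0.5, step_up_factor = 2,
      initial_value = 25, floor = 0.01, ceiling = 100,
      harder_direction = "decrease"),
    attr = staircase_config(
      name = "attr", step_down_factor = 0.5, step_up_factor = 2,
      initial_value = 10, floor = 0.1, ceiling = 100,
      harder_direction = "decrease"),
    mdt = staircase_config(
      name = "mdt", step_down_factor = 1 / 1.25, step_up_factor = 1.25,
      initial_value = 0.5, floor = 0.001, ceiling = 1,
      harder_direction = "decrease",
      n_reversals_stop = 4, n_reversals_use = 2, report_db = TRUE)
  )
}

#' Initialize a track state
#'
#' @param config a [staircase_config()].
#' @return A `track_state` list: current value, run counter, last step
#'   direction, reversal values, trial log and status.
#' @export
new_track <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(config = config,
         current_value = config$initial_value,
         run_correct = 0L,
         last_step_direction = "none",
         reversal_values = numeric(0),
         trial_value = numeric(0),
         trial_correct = logical(0),
         trial_reversal = logical(0),
         pinned_run = 0L,
         status = "running"),
    class = "track_state"
  )
}

# step the value toward harder (+1) or easier (-1); returns clipped value
apply_step <- function(value, direction, config) {
  if (config$step_mode == "multiplicative") {
    f <- if (direction > 0) config$step_down_factor else config$step_up_factor
    v <- value * f
  } else {
    sgn <- if (config$harder_direction == "increase") 1 else -1
    d <- if (direction > 0) config$step_down_factor else -config$step_up_factor
    v <- value + sgn * d
  }
  min(max(v, config$floor), config$ceiling)
}

#' Advance a staircase by one response
#'
#' Applies the transformed up-down rule: after `n_down` consecutive correct
#' responses the value steps toward harder and the run counter resets;
#' after any incorrect response it steps toward easier. A reversal is
#' logged at the pre-step value whenever the step direction flips
#' (including flips while pinned at a bound). The track completes when the
#' reversal quota is met; it is flagged `hit_bound` after 8 consecutive
#' trials pinned at a bound.
#'
#' @param state a `track_state` from [new_track()].
#' @param correct logical response for the presented `current_value`.
#' @return The updated `track_state`.
#' @export
update_track <- function(state, correct) {
  stopifnot(inherits(state, "track_state"))
  if (state$status != "running")
    stop("cannot update a track with status '", state$status, "'")
  config <- state$config
  value <- state$current_value
  state$trial_value <- c(state$trial_value, value)
  state$trial_correct <- c(state$trial_correct, correct)
  reversal_now <- FALSE
  step_dir <- 0L
  if (correct) {
    state$run_correct <- state$run_correct + 1L
    if (state$run_correct >= config$n_down) {
      step_dir <- 1L
      state$run_correct <- 0L
    }
  } else {
    step_dir <- -1L
    state$run_correct <- 0L
  }
  if (step_dir != 0L) {
    dir_label <- if (step_dir > 0) "harder" else "easier"
    if (state$last_step_direction != "none" &&
        state$last_step_direction != dir_label) {
      state$reversal_values <- c(state$reversal_values, value)
      reversal_now <- TRUE
    }
    state$last_step_direction <- dir_label
    state$current_value <- apply_step(value, step_dir, config)
  }
  state$trial_reversal <- c(state$trial_reversal, reversal_now)
  # bound bookkeeping: consecutive trials presented at a bound
  if (value <= config$floor || value >= config$ceiling) {
    state$pinned_run <- state$pinned_run + 1L
  } else {
    state$pinned_run <- 0L
  }
  if (length(state$reversal_values) >= config$n_reversals_stop) {
    state$status <- "complete"
  } else if (state$pinned_run >= 8L) {
    state$status <- "hit_bound"
  } else if (length(state$trial_value) >= config$max_trials) {
    state$status <- "incomplete"
  }
  state
}

#' Threshold from reversal values
#'
#' Geometric or arithmetic mean of the last `n_reversals_use` reversal
#' values. For configurations with `report_db = TRUE` (modulation depth)
#' the geometric-mean depth m is converted to `20 * log10(m)` dB.
#'
#' @param reversals numeric vector of reversal values.
#' @param config a [staircase_config()].
#' @return Threshold in stimulus units (or dB when `report_db`).
#' @export
estimate_threshold <- function(reversals, config) {
  k <- config$n_reversals_use
  if (length(reversals) < k)
    stop("need at least ", k, " reversals to estimate a threshold, have ",
         length(reversals))
  use <- utils::tail(reversals, k)
  est <- if (config$aggregator == "geometric") {
    exp(mean(log(use)))
  } else {
    mean(use)
  }
  if (config$report_db) 20 * log10(est) else est
}

#' Run a closed-loop staircase against a virtual listener
#'
#' Presents `current_value` to the observer trial by trial until the track
#' leaves the running state, then estimates the threshold from the
#' reversal record. Fully reproducible under `seed`.
#'
#' @param config a [staircase_config()].
#' @param observer an [observer_model()].
#' @param seed RNG seed for the response stream.
#' @return A `track_result` list: `threshold` (NA when the reversal quota
#'   was not met), `threshold_linear` (pre-dB-conversion value), `n_trials`,
#'   `reversal_values`, `hit_bound`, `complete`, `config_id`, and the trial
#'   log as a data frame.
#' @export
run_track <- function(config, observer, seed = 1) {
  stopifnot(inherits(config, "staircase_config"),
            inherits(observer, "observer_model"))
  state <- new_track(config)
  state <- with_seed(seed, {
    s <- state
    while (s$status == "running") {
      s <- update_track(s, respond(s$current_value, observer))
    }
    s
  })
  complete <- state$status == "complete"
  threshold <- NA_real_
  threshold_linear <- NA_real_
  if (length(state$reversal_values) >= config$n_reversals_use) {
    threshold <- estimate_threshold(state$reversal_values, config)
    threshold_linear <- if (config$report_db) 10^(threshold / 20) else threshold
  }
  structure(
    list(threshold = threshold,
         threshold_linear = threshold_linear,
         n_trials = length(state$trial_value),
         reversal_values = state$reversal_values,
         hit_bound = state$status == "hit_bound",
         complete = complete,
         config_id = config$name,
         trial_log = data.frame(
           trial = seq_along(state$trial_value),
           value = state$trial_value,
           correct = as.integer(state$trial_correct),
           reversal = as.integer(state$trial_reversal))),
    class = "track_result"
  )
}

#' Export a track's trial log as CSV
#'
#' @param result a `track_result` from [run_track()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_log <- function(result, path) {
  utils::write.csv(result$trial_log, path, row.names = FALSE)
  invisible(path)
}
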