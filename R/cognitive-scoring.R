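#' Attention Network Test design
#'
#' Emits the 120-trial single block: the 3 (cue: none / center / spatial)
#' x 3 (congruency) x 2 (position) x 2 (direction) = 36 factor cells are
#' filled three times each (108 trials) and the remaining 12 trials are
#' distributed one per no-cue cell, then the block is shuffled under
#' `seed`.
#'
#' @param seed RNG seed for the shuffle.
#' @return A 120-row data frame: `cue`, `congruency`, `position`,
#'   `direction`.
#' @export
ant_design <- function(seed = 1) {
  cells <- expand.grid(
    cue = c("none", "center", "spatial"),
    congruency = c("congruent", "incongruent", "neutral"),
    position = c("above", "below"),
    direction = c("left", "right"),
    stringsAsFactors = FALSE)
  design <- cells[rep(seq_len(nrow(cells)), 3), ]
  extra <- cells[cells$cue == "none", ]           # 12 cells, one extra each
  design <- rbind(design, extra)
  design <- with_seed(seed, design[sample(nrow(design)), ])
  rownames(design) <- NULL
  design
}

#' Attention network effects
#'
#' Computes the three RT-difference scores from trial records, using
#' correct trials only: alerting = mean RT(no cue) - mean RT(center cue);
#' orienting = mean RT(center cue) - mean RT(spatial cue); conflict =
#' mean RT(incongruent) - mean RT(congruent).
#'
#' @param trials data frame with columns `cue`, `congruency`, `rt_ms`,
#'   `correct`.
#' @return A list with `alerting`, `orienting`, `conflict` (ms).
#' @export
ant_effects <- function(trials) {
  need <- c("cue", "congruency", "rt_ms", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lack columns: ", paste(miss, collapse = ", "))
  ok <- trials[as.logical(trials$correct), , drop = FALSE]
  mean_rt <- function(filter, label) {
    rt <- ok$rt_ms[filter]
    if (!length(rt)) stop("no correct trials in condition '", label, "'")
    mean(rt)
  }
  list(
    alerting = mean_rt(ok$cue == "none", "no cue") -
      mean_rt(ok$cue == "center", "center cue"),
    orienting = mean_rt(ok$cue == "center", "center cue") -
      mean_rt(ok$cue == "spatial", "spatial cue"),
    conflict = mean_rt(ok$congruency == "incongruent", "incongruent") -
      mean_rt(ok$congruency == "congruent", "congruent"))
}

#' Mental Rotation Test design
#'
#' 100 trials: 5 letters (F, G, L, P, R) x 4 conditions (standard,
#' mirrored, and both forms rotated) x 5 cycles, shuffled under `seed`.
#' Rotated conditions get a random angle per trial.
#'
#' @param seed RNG seed.
#' @return A 100-row data frame: `letter`, `condition`, `mirror`
#'   (logical), `angle_deg`.
#' @export
mrt_design <- function(seed = 1) {
  base <- expand.grid(
    letter = c("F", "G", "L", "P", "R"),
    condition = c("standard", "mirrored", "standard_rotated",
                  "mirrored_rotated"),
    cycle = 1:5,
    stringsAsFactors = FALSE)
  with_seed(seed, {
    base$angle_deg <- ifelse(grepl("rotated", base$condition),
                             round(runif(nrow(base), 15, 345)), 0)
    base$mirror <- grepl("mirrored", base$condition)
    out <- base[sample(nrow(base)), c("letter", "condition", "mirror",
                                      "angle_deg")]
    rownames(out) <- NULL
    out
  })
}

#' Score Mental Rotation Test trials
#'
#' Accuracy (%) and mean RT (ms) within the mirror and non-mirror classes,
#' with rotation collapsed. Timeouts count as incorrect and are excluded
#' from RT means.
#'
#' @param trials data frame with columns `mirror` (logical), `correct`,
#'   `rt_ms`, and optionally `timeout`.
#' @return A list with `mirror_acc`, `nonmirror_acc` (percent),
#'   `mirror_rt`, `nonmirror_rt` (ms over correct trials).
#' @export
score_mrt <- function(trials) {
  need <- c("mirror", "correct", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lack columns: ", paste(miss, collapse = ", "))
  timeout <- if ("timeout" %in% names(trials)) as.logical(trials$timeout)
             else rep(FALSE, nrow(trials))
  correct <- as.logical(trials$correct) & !timeout
  class_score <- function(is_mirror) {
    idx <- trials$mirror == is_mirror
    if (!any(idx)) stop("no trials in the ",
                        if (is_mirror) "mirror" else "non-mirror", " class")
    acc <- 100 * sum(correct[idx]) / sum(idx)
    rt_idx <- idx & correct
    rt <- if (any(rt_idx)) mean(trials$rt_ms[rt_idx]) else NA_real_
    list(acc = acc, rt = rt)
  }
  m <- class_score(TRUE); nm <- class_score(FALSE)
  list(mirror_acc = m$acc, nonmirror_acc = nm$acc,
       mirror_rt = m$rt, nonmirror_rt = nm$rt)
}

#' Initialize an adaptive digit-span state
#'
#' Sequences run from 2 to 8 digits. A correct recall lengthens the next
#' sequence by one; an incorrect recall repeats the length once, and a
#' second failure at the same length terminates the test with the span
#' equal to the longest correctly recalled length.
#'
#' @param start_length first sequence length.
#' @return A `digit_span_state` list.
#' @export
digit_span_new <- function(start_length = 2) {
  if (start_length < 2 || start_length > 8)
    stop("start_length must lie in 2..8")
  structure(
    list(current_length = as.integer(start_length),
         failures_at_length = 0L, longest_correct = 0L,
         n_steps = 0L, terminated = FALSE),
    class = "digit_span_state"
  )
}

#' Advance the adaptive digit-span procedure
#'
#' @param state a `digit_span_state`.
#' @param correct was the current sequence recalled correctly?
#' @return The updated state; `terminated` is `TRUE` once the participant
#'   fails twice at one length or succeeds at the 8-digit maximum, and
#'   `longest_correct` then holds the span.
#' @export
digit_span_step <- function(state, correct) {
  stopifnot(inherits(state, "digit_span_state"))
  if (state$terminated) stop("digit span procedure already terminated")
  state$n_steps <- state$n_steps + 1L
  if (correct) {
    state$longest_correct <- max(state$longest_correct, state$current_length)
    state$failures_at_length <- 0L
    if (state$current_length >= 8L) {
      state$terminated <- TRUE
    } else {
      state$current_length <- state$current_length + 1L
    }
  } else {
    state$failures_at_length <- state$failures_at_length + 1L
    if (state$failures_at_length >= 2L) state$terminated <- TRUE
  }
  state
}

#' Simulate ANT trial records
#'
#' Attaches reaction times and accuracy to an [ant_design()] block:
#' RT = `base_rt` + cue cost + congruency cost + Gaussian noise, truncated
#' to the 2000-ms response window.
#'
#' @param design an [ant_design()] data frame.
#' @param base_rt mean RT (ms) in the spatial-cue congruent condition.
#' @param alerting,orienting,conflict planted effect sizes (ms).
#' @param sd_rt trial-to-trial RT standard deviation (ms).
#' @param p_correct probability a trial is answered correctly.
#' @param seed RNG seed.
#' @return The design with `rt_ms` and `correct` columns added.
#' @export
simulate_ant_trials <- function(design, base_rt = 550, alerting = 30,
                                orienting = 40, conflict = 90, sd_rt = 60,
                                p_correct = 0.95, seed = 1) {
  with_seed(seed, {
    cue_cost <- c(none = alerting + orienting, center = orienting,
                  spatial = 0)[design$cue]
    congr_cost <- c(congruent = 0, neutral = conflict / 2,
                    incongruent = conflict)[design$congruency]
    rt <- base_rt + cue_cost + congr_cost + rnorm(nrow(design), sd = sd_rt)
    design$rt_ms <- pmin(pmax(rt, 150), 2000)
    design$correct <- runif(nrow(design)) < p_correct
    design
  })
}
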