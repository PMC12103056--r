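#' Speech-in-noise (QuickSIN) SNR loss
#'
#' Scores one QuickSIN list: seven sentences of five keywords each,
#' presented at SNRs descending from +8 dB to -10 dB in 3-dB steps.
#' SNR loss in dB is `22.5 - total keywords correct`.
#'
#' @param keywords_correct integer vector of length 7; keywords correct per
#'   sentence, each in 0..5, ordered from +8 dB down to -10 dB SNR.
#' @return SNR loss in dB (range -12.5 to 22.5).
#' @export
quicksin_snr_loss <- function(keywords_correct) {
  if (length(keywords_correct) != 7)
    stop("QuickSIN needs exactly 7 sentence scores (one per SNR level), got ",
         length(keywords_correct))
  if (any(keywords_correct < 0 | keywords_correct > 5) ||
      any(keywords_correct != round(keywords_correct)))
    stop("each sentence score must be an integer in 0..5")
  22.5 - sum(keywords_correct)
}

#' SNR levels of the QuickSIN list
#'
#' @return The seven per-sentence SNRs in dB, from +8 to -10 in -3 dB steps.
#' @export
quicksin_snr_levels <- function() seq(8, -10, by = -3)

#' Dichotic digit test trials
#'
#' Builds a validated data frame of DDT trials. Each trial presents two
#' distinct digits to each ear; `recalled` holds the participant's report
#' as a semicolon-joined string (free recall is order-blind; forced-ear
#' scoring only inspects the attended ear's digits).
#'
#' @param presented_right,presented_left lists (or 2-column matrices) of the
#'   two digits per ear.
#' @param recalled list of integer vectors (the digits reported).
#' @param condition `"free"`, `"forced_right"` or `"forced_left"` (recycled).
#' @return A data frame of class `ddt_trials`.
#' @export
ddt_trials <- function(presented_right, presented_left, recalled,
                       condition = "free") {
  as_pairs <- function(x) {
    if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    x
  }
  pr <- as_pairs(presented_right); pl <- as_pairs(presented_left)
  n <- length(pr)
  if (length(pl) != n || length(recalled) != n)
    stop("presented_right, presented_left and recalled must have equal length")
  condition <- rep_len(condition, n)
  ok <- condition %in% c("free", "forced_right", "forced_left")
  if (!all(ok)) stop("unknown DDT condition: ", condition[!ok][1])
  for (i in seq_len(n)) {
    if (length(pr[[i]]) != 2 || length(pl[[i]]) != 2)
      stop("trial ", i, ": exactly two digits per ear are required")
  }
  structure(
    data.frame(
      trial = seq_len(n),
      condition = condition,
      right1 = vapply(pr, `[`, numeric(1), 1),
      right2 = vapply(pr, `[`, numeric(1), 2),
      left1 = vapply(pl, `[`, numeric(1), 1),
      left2 = vapply(pl, `[`, numeric(1), 2),
      recalled = vapply(recalled, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE),
    class = c("ddt_trials", "data.frame")
  )
}

recalled_digits <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])

# how many of the two presented digits appear in the recalled multiset
n_recalled_from_ear <- function(d1, d2, recalled) {
  pool <- recalled
  n <- 0L
  for (d in c(d1, d2)) {
    hit <- match(d, pool)
    if (!is.na(hit)) {
      n <- n + 1L
      pool <- pool[-hit]
    }
  }
  n
}

#' Score free-recall dichotic digit trials
#'
#' Per trial: a Double Correct Score (DCS) point when all four digits are
#' recalled; a Total R point when both right-ear digits are recalled along
#' with one or no left-ear digits; Total L symmetrically. The Right Ear
#' Advantage is `Total R - Total L`. The three counters are mutually
#' exclusive on any trial. Recall is order-blind.
#'
#' @param trials a [ddt_trials()] data frame, all in the free condition.
#' @return A list with `dcs`, `total_r`, `total_l`, `rea`, `n_trials`.
#' @export
score_ddt_free <- function(trials) {
  if (!all(trials$condition == "free"))
    stop("score_ddt_free expects only free-recall trials")
  dcs <- 0L; total_r <- 0L; total_l <- 0L
  for (i in seq_len(nrow(trials))) {
    rec <- recalled_digits(trials$recalled[i])
    nr <- n_recalled_from_ear(trials$right1[i], trials$right2[i], rec)
    nl <- n_recalled_from_ear(trials$left1[i], trials$left2[i], rec)
    if (nr == 2 && nl == 2) {
      dcs <- dcs + 1L
    } else if (nr == 2 && nl <= 1) {
      total_r <- total_r + 1L
    } else if (nl == 2 && nr <= 1) {
      total_l <- total_l + 1L
    }
  }
  list(dcs = dcs, total_r = total_r, total_l = total_l,
       rea = total_r - total_l, n_trials = nrow(trials))
}

#' Score forced-attention dichotic digit trials
#'
#' One point per trial in which both digits presented to the attended ear
#' are correctly reported.
#'
#' @param trials a [ddt_trials()] data frame in the matching forced
#'   condition.
#' @param ear `"right"` or `"left"`.
#' @return Count of fully correct attended-ear trials.
#' @export
score_ddt_forced <- function(trials, ear = c("right", "left")) {
  ear <- match.arg(ear)
  want <- paste0("forced_", ear)
  if (nrow(trials) > 0 && !all(trials$condition == want))
    stop("score_ddt_forced(ear = '", ear, "') expects only ", want, " trials")
  n <- 0L
  for (i in seq_len(nrow(trials))) {
    rec <- recalled_digits(trials$recalled[i])
    hits <- if (ear == "right")
      n_recalled_from_ear(trials$right1[i], trials$right2[i], rec)
    else
      n_recalled_from_ear(trials$left1[i], trials$left2[i], rec)
    if (hits == 2) n <- n + 1L
  }
  n
}

#' Simulate dichotic digit trials for a virtual participant
#'
#' Draws distinct digit pairs (1..9) per ear and simulates order-blind
#' recall in which each right-ear digit is recalled with probability
#' `p_right` and each left-ear digit with probability `p_left`
#' (independently). Used to build symbolic trial records for scoring; no
#' audio is involved.
#'
#' @param n_trials trials per condition.
#' @param p_right,p_left per-digit recall probabilities.
#' @param condition DDT condition for the generated block.
#' @param seed RNG seed.
#' @return A [ddt_trials()] data frame.
#' @export
simulate_ddt_trials <- function(n_trials = 20, p_right = 0.9, p_left = 0.9,
                                condition = "free", seed = 1) {
  with_seed(seed, {
    pr <- vector("list", n_trials); pl <- vector("list", n_trials)
    rec <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      digs <- sample(1:9, 4)
      pr[[i]] <- digs[1:2]; pl[[i]] <- digs[3:4]
      got_r <- pr[[i]][runif(2) < p_right]
      got_l <- pl[[i]][runif(2) < p_left]
      rec[[i]] <- switch(condition,
        free = sample(c(got_r, got_l)),
        forced_right = got_r,
        forced_left = got_l)
      if (length(rec[[i]]) == 0) rec[[i]] <- sample(1:9, 1) # a guess
    }
    ddt_trials(pr, pl, rec, condition)
  })
}
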