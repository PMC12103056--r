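#' Psychometric virtual listener
#'
#' A simulated observer answering forced-choice staircase trials. The
#' probability of a correct response follows a logistic psychometric
#' function on the log10-stimulus axis,
#' `p(x) = gamma + (1 - gamma - lapse) * F(s * (log10 x - log10 theta) / slope)`,
#' where `gamma` is the chance rate of the m-interval forced choice,
#' `lapse` the stimulus-independent error rate, and the sign `s` is chosen
#' so that moving the stimulus in the track's harder direction lowers p.
#' `theta` is therefore the stimulus value at which performance is halfway
#' between chance and `1 - lapse`.
#'
#' @param theta true threshold in stimulus units (> 0).
#' @param slope psychometric spread in log10-stimulus units (> 0).
#' @param guess chance rate gamma (1 / number of intervals).
#' @param lapse lapse rate lambda in \[0, 0.1\].
#' @param harder_direction `"increase"` or `"decrease"`: whether raising the
#'   stimulus value makes the task harder.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(theta, slope = 0.15, guess = 1 / 3, lapse = 0.02,
                           harder_direction = c("decrease", "increase")) {
  harder_direction <- match.arg(harder_direction)
  if (theta <= 0) stop("theta must be positive (log-domain psychometric)")
  if (slope <= 0) stop("slope must be positive")
  if (guess <= 0 || guess >= 1) stop("guess rate must lie in (0, 1)")
  if (lapse < 0 || lapse > 0.1) stop("lapse must lie in [0, 0.1]")
  structure(
    list(theta = theta, slope = slope, guess = guess, lapse = lapse,
         harder_direction = harder_direction),
    class = "observer_model"
  )
}

#' Probability of a correct response at a stimulus value
#'
#' @param x stimulus value (> 0).
#' @param observer an [observer_model()].
#' @return Probability of a correct response, in `[guess, 1 - lapse]`.
#' @export
p_correct <- function(x, observer) {
  stopifnot(inherits(observer, "observer_model"))
  if (any(x <= 0)) stop("stimulus value must be positive")
  s <- if (observer$harder_direction == "increase") -1 else 1
  z <- s * (log10(x) - log10(observer$theta)) / observer$slope
  observer$guess + (1 - observer$guess - observer$lapse) * plogis(z)
}

#' Simulate one trial response
#'
#' Bernoulli draw with probability [p_correct()]. Uses the current RNG
#' stream; seed it (e.g. inside [run_track()]) for reproducibility.
#'
#' @inheritParams p_correct
#' @return Logical: was the response correct?
#' @export
respond <- function(x, observer) {
  runif(1) < p_correct(x, observer)
}

#' Stimulus value at a target probability correct
#'
#' Inverts the psychometric function; used to locate the 70.7%-correct
#' point that a 2-down-1-up track converges to.
#'
#' @param observer an [observer_model()].
#' @param p target probability (must lie strictly between `guess` and
#'   `1 - lapse`).
#' @return Stimulus value x with `p_correct(x, observer) == p`.
#' @export
threshold_at_p <- function(observer, p = 0.707) {
  stopifnot(inherits(observer, "observer_model"))
  fmax <- 1 - observer$guess - observer$lapse
  frac <- (p - observer$guess) / fmax
  if (frac <= 0 || frac >= 1)
    stop("target p = ", p, " is outside the attainable range")
  s <- if (observer$harder_direction == "increase") -1 else 1
  z <- qlogis(frac)
  10^(log10(observer$theta) + s * observer$slope * z)
}
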