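#' Stimulus synthesis for the temporal-processing tests
#'
#' Four stimulus families are used by the adaptive battery: interaural-phase
#' tone sequences (TFS-AF), frequency-modulated tones (FMDL), gap-in-noise
#' (ATTR) and amplitude-modulated noise (MDT). All are synthesized at
#' 44.1 kHz. Presentation levels (dB SPL / dB SL) are metadata of the
#' protocol, not of the digital waveform: tonal buffers are peak-normalized
#' to 0.9 and noise carriers use a fixed RMS so that modulation depth is the
#' only level cue.
#'
#' @name stimuli
NULL

# Evaluate expr with a private RNG stream; global .Random.seed is restored.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Interaural-phase tone-sequence interval specification
#'
#' One TFS-AF interval is four consecutive 400-ms pure tones separated by
#' 100-ms silences (1900 ms total). In the standard interval every tone is
#' diotic (interaural phase 0 deg); in the target interval tones 2 and 4
#' carry a 180-deg interaural phase difference.
#'
#' @param frequency tone frequency in Hz (200 to 4000).
#' @param target if `TRUE`, tones 2 and 4 get a 180 deg IPD.
#' @param ipd_pattern per-tone interaural phase in degrees (length 4);
#'   overrides `target` when given.
#' @param tone_dur_ms,gap_ms tone and inter-tone silence durations (ms).
#' @param level_db_sl nominal presentation level in dB SL (metadata only).
#' @return A list of class `tfs_interval_spec`.
#' @export
tfs_interval_spec <- function(frequency, target = FALSE, ipd_pattern = NULL,
                              tone_dur_ms = 400, gap_ms = 100,
                              level_db_sl = 30) {
  if (frequency < 200 || frequency > 4000)
    stop("frequency must lie in [200, 4000] Hz, got ", frequency)
  if (is.null(ipd_pattern))
    ipd_pattern <- if (target) c(0, 180, 0, 180) else c(0, 0, 0, 0)
  if (length(ipd_pattern) != 4)
    stop("ipd_pattern must give an interaural phase for exactly 4 tones")
  structure(
    list(frequency = frequency, ipd_pattern = ipd_pattern,
         tone_dur_ms = tone_dur_ms, gap_ms = gap_ms,
         level_db_sl = level_db_sl),
    class = "tfs_interval_spec"
  )
}

#' Synthesize one TFS-AF interval
#'
#' @param spec a [tfs_interval_spec()].
#' @param sample_rate sampling rate in Hz.
#' @param ramp_ms raised-cosine on/off ramp per tone (ms).
#' @return A two-channel [audio_buffer()] of duration
#'   `4 * tone_dur_ms + 3 * gap_ms` (1900 ms with defaults).
#' @export
synth_tfs_interval <- function(spec, sample_rate = 44100, ramp_ms = 10) {
  stopifnot(inherits(spec, "tfs_interval_spec"))
  fs <- sample_rate
  n_tone <- round(spec$tone_dur_ms * fs / 1000)
  n_gap <- round(spec$gap_ms * fs / 1000)
  t <- (seq_len(n_tone) - 1) / fs
  env <- raised_cosine_env(n_tone, ramp_ms, fs)
  left <- numeric(0); right <- numeric(0)
  silence <- numeric(n_gap)
  for (k in 1:4) {
    phi <- spec$ipd_pattern[k] * pi / 180
    l <- sin(2 * pi * spec$frequency * t) * env
    r <- sin(2 * pi * spec$frequency * t + phi) * env
    left <- c(left, l)
    right <- c(right, r)
    if (k < 4) {
      left <- c(left, silence)
      right <- c(right, silence)
    }
  }
  samples <- peak_normalize(cbind(left, right, deparse.level = 0))
  audio_buffer(samples, sample_rate = fs)
}

#' Synthesize a sinusoidally frequency-modulated tone
#'
#' Instantaneous frequency is `carrier_hz + depth_hz * sin(2 pi rate_hz t)`.
#' `depth_hz = 0` gives a pure tone.
#'
#' @param depth_hz peak frequency excursion in Hz (>= 0).
#' @param carrier_hz carrier frequency in Hz.
#' @param rate_hz modulation rate in Hz.
#' @param dur_ms duration in ms.
#' @param sample_rate sampling rate in Hz.
#' @param ramp_ms raised-cosine on/off ramp (ms).
#' @return A mono [audio_buffer()].
#' @export
synth_fm_tone <- function(depth_hz, carrier_hz = 500, rate_hz = 2,
                          dur_ms = 1250, sample_rate = 44100, ramp_ms = 10) {
  if (depth_hz < 0) stop("modulation depth_hz must be >= 0, got ", depth_hz)
  fs <- sample_rate
  n <- round(dur_ms * fs / 1000)
  t <- (seq_len(n) - 1) / fs
  # phase whose derivative is 2*pi*(carrier + depth*sin(2*pi*rate*t))
  phase <- 2 * pi * carrier_hz * t -
    (depth_hz / rate_hz) * cos(2 * pi * rate_hz * t)
  x <- sin(phase) * raised_cosine_env(n, ramp_ms, fs)
  audio_buffer(peak_normalize(x), sample_rate = fs)
}

#' Synthesize broadband noise with a centered silent gap
#'
#' White Gaussian noise with a silent gap of `gap_ms` centered in the
#' buffer; 1-ms raised-cosine ramps shape the gap edges so the gap itself,
#' not a spectral splatter click, is the detection cue. `gap_ms = 0`
#' yields continuous noise.
#'
#' @param gap_ms gap duration in ms (0 <= gap_ms < dur_ms).
#' @param dur_ms total buffer duration in ms.
#' @param seed RNG seed for the noise carrier.
#' @param sample_rate sampling rate in Hz.
#' @return A mono [audio_buffer()].
#' @export
synth_gap_noise <- function(gap_ms, dur_ms = 500, seed = 1,
                            sample_rate = 44100) {
  if (gap_ms < 0 || gap_ms >= dur_ms)
    stop("gap_ms must satisfy 0 <= gap_ms < dur_ms, got ", gap_ms)
  fs <- sample_rate
  n <- round(dur_ms * fs / 1000)
  x <- with_seed(seed, rnorm(n))
  if (gap_ms > 0) {
    n_gap <- round(gap_ms * fs / 1000)
    i0 <- floor((n - n_gap) / 2) + 1L   # first silent sample
    env <- rep(1, n)
    env[i0:(i0 + n_gap - 1L)] <- 0
    n_ramp <- max(1L, round(1 * fs / 1000))   # 1-ms edge ramps
    down <- 0.5 * (1 + cos(pi * seq_len(n_ramp) / n_ramp))
    pre <- (i0 - n_ramp):(i0 - 1L)
    post <- (i0 + n_gap):(i0 + n_gap + n_ramp - 1L)
    pre <- pre[pre >= 1]; post <- post[post <= n]
    env[pre] <- down[seq_along(pre)]
    env[post] <- rev(down)[seq_along(post)]
    x <- x * env
  }
  audio_buffer(peak_normalize(x), sample_rate = fs)
}

#' Synthesize sinusoidally amplitude-modulated noise
#'
#' White Gaussian noise multiplied by `(1 + m sin(2 pi rate_hz t))`, then
#' rescaled to a fixed RMS of 0.08 so that the realized level is identical
#' across modulation depths: overall level carries no information about
#' the target interval, only the modulation does. Peak normalization is
#' deliberately not used here for the same reason.
#'
#' @param depth_m modulation depth m in \[0, 1\].
#' @param rate_hz modulation rate in Hz.
#' @param dur_ms duration in ms.
#' @param seed RNG seed for the noise carrier.
#' @param sample_rate sampling rate in Hz.
#' @return A mono [audio_buffer()].
#' @export
synth_am_noise <- function(depth_m, rate_hz = 8, dur_ms = 500, seed = 1,
                           sample_rate = 44100) {
  if (depth_m < 0 || depth_m > 1)
    stop("depth_m must lie in [0, 1], got ", depth_m)
  fs <- sample_rate
  n <- round(dur_ms * fs / 1000)
  t <- (seq_len(n) - 1) / fs
  carrier <- with_seed(seed, rnorm(n))
  x <- carrier * (1 + depth_m * sin(2 * pi * rate_hz * t))
  x <- x * (0.08 / sqrt(mean(x^2)))
  x <- pmax(-1, pmin(1, x))
  audio_buffer(x, sample_rate = fs)
}
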