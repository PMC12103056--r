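test_that("audio buffers enforce finiteness, range and channel count", {
  expect_error(audio_buffer(c(0, 2)), "\\[-1, 1\\]")
  expect_error(audio_buffer(c(0, NaN)), "finite")
  expect_error(audio_buffer(matrix(0, 4, 3)), "channel")
  b <- audio_buffer(sin(2 * pi * 440 * (0:4409) / 44100))
  expect_equal(n_samples(b), 4410)
  expect_equal(duration_ms(b), 100)
})

test_that("WAV files round-trip sample and channel counts", {
  b <- synth_tfs_interval(tfs_interval_spec(500, target = TRUE))
  path <- tempfile(fileext = ".wav")
  write_wav(b, path)
  b2 <- read_wav(path)
  expect_equal(n_samples(b2), n_samples(b))
  expect_equal(n_channels(b2), 2)
  expect_equal(b2$sample_rate, 44100)
  # 16-bit quantization error bounded
  expect_lt(max(abs(b2$samples - b$samples)), 1 / 32000)
})

test_that("standard interaural-phase interval is diotic and has the printed duration", {
  b <- synth_tfs_interval(tfs_interval_spec(200))
  expect_identical(b$samples[, 1], b$samples[, 2])
  # 4 x 400 ms tones + 3 x 100 ms silences = 1.9 s
  expect_equal(n_samples(b), round(1.9 * 44100))
  expect_equal(n_samples(b), 83790)
  expect_error(tfs_interval_spec(100), "\\[200, 4000\\]")
  expect_error(tfs_interval_spec(5000), "\\[200, 4000\\]")
})

test_that("target interval carries a half-period interaural lag in tones 2 and 4", {
  f <- 500
  b <- synth_tfs_interval(tfs_interval_spec(f, target = TRUE))
  fs <- b$sample_rate
  # central part of tone 2 (skip ramps): tone 2 starts at 500 ms
  i0 <- round(0.5 * fs) + round(0.05 * fs)
  idx <- i0:(i0 + round(0.3 * fs))
  l <- b$samples[idx, 1]; r <- b$samples[idx, 2]
  lags <- -60:60
  cc <- vapply(lags, function(k) {
    sum(l * c(rep(0, max(0, k)), head(r, length(r) - abs(k)),
              rep(0, max(0, -k)))[seq_along(l)])
  }, numeric(1))
  best <- lags[which.max(cc)]
  half_period_samples <- fs / f / 2   # 44.1 samples at 500 Hz
  expect_lte(abs(abs(best) - half_period_samples), 1)
  # tones 1 and 3 remain diotic
  j0 <- round(0.05 * fs)
  expect_identical(b$samples[j0:(j0 + 1000), 1], b$samples[j0:(j0 + 1000), 2])
})

test_that("FM tone has the printed length and a pure spectrum at depth 0", {
  b <- synth_fm_tone(0)
  expect_equal(n_samples(b), 55125)      # 1.25 s at 44.1 kHz
  spec <- Mod(stats::fft(b$samples[, 1]))
  half <- spec[1:(length(spec) / 2)]
  peak_hz <- (which.max(half) - 1) / 1.25
  expect_equal(peak_hz, 500, tolerance = 1)
  expect_error(synth_fm_tone(-1), "depth")
})

test_that("FM instantaneous frequency spans carrier +/- depth", {
  b <- synth_fm_tone(25)
  fi <- instantaneous_frequency(b$samples[, 1], b$sample_rate)
  core <- fi[2000:(length(fi) - 2000)]   # skip onset/offset ramps
  expect_equal(min(core), 475, tolerance = 1)
  expect_equal(max(core), 525, tolerance = 1)
})

test_that("gap noise is silent inside the gap and continuous without one", {
  fs <- 44100
  b <- synth_gap_noise(10, dur_ms = 500, seed = 7)
  n <- n_samples(b)
  n_gap <- round(10 * fs / 1000)
  expect_equal(n_gap, 441)
  i0 <- floor((n - n_gap) / 2) + 1
  gap_rms <- sqrt(mean(b$samples[i0:(i0 + n_gap - 1), 1]^2))
  flank_rms <- sqrt(mean(b$samples[1:(i0 - 500), 1]^2))
  expect_lt(gap_rms, 0.01 * flank_rms)
  # no gap: no 5-ms window falls below 10% of overall RMS
  b0 <- synth_gap_noise(0, dur_ms = 500, seed = 7)
  x <- b0$samples[, 1]
  w <- round(0.005 * fs)
  starts <- seq(1, length(x) - w, by = w %/% 2)
  win_rms <- vapply(starts, function(s) sqrt(mean(x[s:(s + w - 1)]^2)),
                    numeric(1))
  expect_gt(min(win_rms), 0.1 * sqrt(mean(x^2)))
  expect_error(synth_gap_noise(500, dur_ms = 400), "gap_ms")
})

test_that("synthesis is a pure function of parameters and seed", {
  expect_identical(synth_gap_noise(10, seed = 3)$samples,
                   synth_gap_noise(10, seed = 3)$samples)
  expect_identical(synth_am_noise(0.5, seed = 3)$samples,
                   synth_am_noise(0.5, seed = 3)$samples)
  expect_false(identical(synth_gap_noise(10, seed = 3)$samples,
                         synth_gap_noise(10, seed = 4)$samples))
})

test_that("AM noise is RMS-equalized across depths and recovers its depth", {
  rms <- function(b) sqrt(mean(b$samples^2))
  r0 <- rms(synth_am_noise(0, seed = 11))
  r9 <- rms(synth_am_noise(0.9, seed = 11))
  expect_gt(r9 / r0, 0.99)
  expect_lt(r9 / r0, 1.01)
  b <- synth_am_noise(0.5, seed = 11)
  expect_equal(n_samples(b), 22050)      # 500 ms
  m_hat <- fit_am_depth(b$samples[, 1], b$sample_rate, 8)
  expect_equal(m_hat, 0.5, tolerance = 0.05)
  expect_error(synth_am_noise(1.2), "\\[0, 1\\]")
})

test_that("every synthesized buffer respects the container invariants", {
  bufs <- list(
    synth_tfs_interval(tfs_interval_spec(1000, target = TRUE)),
    synth_fm_tone(12), synth_gap_noise(5, seed = 2),
    synth_am_noise(0.8, seed = 2))
  for (b in bufs) {
    expect_true(all(is.finite(b$samples)))
    expect_lte(max(abs(b$samples)), 1)
  }
})
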