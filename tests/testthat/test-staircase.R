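test_that("the 2-down-1-up rule steps and resets as specified", {
  attr_cfg <- battery_staircase_configs()$attr
  s <- new_track(attr_cfg)
  expect_equal(s$current_value, 10)
  s1 <- update_track(s, TRUE)
  expect_equal(s1$current_value, 10)      # one correct: run counter only
  expect_equal(s1$run_correct, 1L)
  s2 <- update_track(s1, TRUE)
  expect_equal(s2$current_value, 5)       # two corrects: gap halves
  expect_equal(s2$run_correct, 0L)
  s3 <- update_track(s2, FALSE)
  expect_equal(s3$current_value, 10)      # incorrect: doubles back
  expect_length(s3$reversal_values, 1)    # direction flipped once
  expect_equal(s3$reversal_values, 5)     # reversal logged at the turn
})

test_that("track values never leave the configured bounds", {
  cfg <- staircase_config(step_down_factor = 0.5, step_up_factor = 2,
                          initial_value = 1, floor = 0.5, ceiling = 4,
                          harder_direction = "decrease")
  s <- new_track(cfg)
  set.seed(99)
  for (i in 1:60) {
    if (s$status != "running") break
    s <- update_track(s, runif(1) < 0.5)
  }
  expect_true(all(s$trial_value >= cfg$floor & s$trial_value <= cfg$ceiling))
  expect_error(update_track(s, TRUE), "status")
})

test_that("threshold estimation matches closed forms", {
  cfg <- battery_staircase_configs()$attr
  expect_equal(estimate_threshold(c(4, 8, 4, 8, 4, 8), cfg), sqrt(32))
  expect_equal(estimate_threshold(rep(3, 8), cfg), 3)
  arith <- staircase_config(step_down_factor = 0.5, step_up_factor = 2,
                            initial_value = 1, floor = 0.1, ceiling = 10,
                            harder_direction = "decrease",
                            aggregator = "arithmetic")
  expect_equal(estimate_threshold(rep(3, 8), arith), 3)
  expect_equal(estimate_threshold(c(4, 8, 4, 8, 4, 8), arith), 6)
  # geometric mean is exp(mean(log)) to machine precision
  r <- c(2.3, 7.1, 0.9, 4.4, 1.2, 6.6)
  expect_equal(estimate_threshold(r, cfg), exp(mean(log(r))))
  # modulation-depth track reports dB
  mdt <- battery_staircase_configs()$mdt
  expect_equal(estimate_threshold(c(9, 9, 0.1, 0.2), mdt),
               20 * log10(sqrt(0.02)), tolerance = 1e-10)
  expect_equal(estimate_threshold(c(9, 9, 0.1, 0.2), mdt), -16.9897,
               tolerance = 1e-4)
  expect_error(estimate_threshold(c(1, 2), cfg), "at least 6")
})

test_that("degenerate observers drive tracks to the bounds", {
  cfg <- battery_staircase_configs()$attr
  omniscient <- observer_model(1e-6, slope = 0.01, guess = 1 / 3, lapse = 0,
                               harder_direction = "decrease")
  r <- run_track(cfg, omniscient, seed = 1)
  expect_true(r$hit_bound)
  expect_true(min(r$trial_log$value) <= cfg$floor)
  # descent is monotone until the floor
  vals <- r$trial_log$value
  expect_true(all(diff(vals) <= 0))
  guesser <- observer_model(1e6, slope = 0.01, guess = 1 / 3, lapse = 0.02,
                            harder_direction = "decrease")
  r2 <- run_track(cfg, guesser, seed = 1)
  expect_true(r2$hit_bound)
  expect_equal(max(r2$trial_log$value), cfg$ceiling)
})

test_that("tracks are reproducible and exportable", {
  cfg <- battery_staircase_configs()$fmdl
  obs <- observer_at_x707(5, cfg)
  r1 <- run_track(cfg, obs, seed = 77)
  r2 <- run_track(cfg, obs, seed = 77)
  expect_identical(r1$trial_log, r2$trial_log)
  expect_identical(r1$threshold, r2$threshold)
  path <- tempfile(fileext = ".csv")
  write_track_log(r1, path)
  log <- read.csv(path)
  expect_named(log, c("trial", "value", "correct", "reversal"))
  expect_equal(nrow(log), r1$n_trials)
})

test_that("simulated tracks recover the 70.7% point of each test protocol", {
  # Parameter-recovery property: per configuration, the median of 200
  # simulated thresholds lies within 15% (log scale) of the observer's
  # 70.7%-correct stimulus value.
  configs <- battery_staircase_configs()
  targets <- c(tfs_af = 290, fmdl = 5, attr = 8, mdt = 0.38)
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    obs <- observer_at_x707(targets[[nm]], cfg)
    th <- vapply(1:200, function(i) {
      run_track(cfg, obs, seed = 5000 + i)$threshold_linear
    }, numeric(1))
    err <- abs(median(log10(th)) - log10(targets[[nm]]))
    expect_lt(err, log10(1.15))
  }
})

test_that("the staircase engine converges to the 70.7% point", {
  # Engine-level convergence with the gap-detection rule, started near
  # threshold: geometric-mean estimate within 5% of the 70.7% point
  # (Monte-Carlo tolerance for 300 tracks).
  cfg <- battery_staircase_configs()$attr
  obs <- observer_at_x707(8, cfg)
  th <- vapply(1:300, function(i) {
    run_track(cfg, obs, seed = 900 + i)$threshold_linear
  }, numeric(1))
  expect_lt(abs(mean(log10(th)) - log10(8)), log10(1.05))
})
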