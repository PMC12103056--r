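#' Calibration profile for the synthetic cohort
#'
#' Per-measure, per-group target median and interquartile range together
#' with the marginal distribution family and the planted latent-factor
#' assignment. The default profile ships with the package
#' (`inst/extdata/calibration_profile.csv`) and encodes the two-group
#' targets of the study population: an MCI group and a cognitively healthy
#' control group of older adults.
#'
#' Distribution families: `lognormal` (thresholds and reaction times;
#' positive and right-skewed), `normal` (signed quantities such as the
#' modulation detection threshold in dB and the attention effects),
#' `truncnorm` (bounded scores such as PTA and MoCA), `percent`
#' (accuracies clipped to 0-100), `span` (digit span, clipped to 2-8) and
#' `count` (dichotic trial counts, rounded and clipped to 0-20).
#'
#' The planted factors are F1 (temporal-processing / cognitive
#' impairment), F2 (dichotic-listening / attention) and F3 (peripheral
#' hearing); each measure's `loading` gives its correlation with the
#' assigned factor, with the marginal distribution taken from the
#' per-group quantile map.
#'
#' @param path CSV file to read; defaults to the shipped profile.
#' @return A data frame of class `calibration_profile`.
#' @export
default_calibration <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "calibration_profile.csv",
                        package = "capsim", mustWork = TRUE)
  prof <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measure", "group", "median", "iqr", "family", "lo", "hi",
            "factor", "loading")
  miss <- setdiff(need, names(prof))
  if (length(miss))
    stop("calibration profile lacks columns: ", paste(miss, collapse = ", "))
  class(prof) <- c("calibration_profile", "data.frame")
  prof
}

# quantile map for one calibrated measure: u in (0,1) -> measure units
calibration_quantile <- function(u, median, iqr, family, lo, hi) {
  z75 <- stats::qnorm(0.75)               # 0.6745
  switch(family,
    lognormal = {
      mu <- log(median)
      ratio <- iqr / median
      a <- (ratio + sqrt(ratio^2 + 4)) / 2  # exp(z75 * sigma)
      sigma <- max(log(a) / z75, 1e-6)
      stats::qlnorm(u, mu, sigma)
    },
    normal = stats::qnorm(u, median, max(iqr / (2 * z75), 1e-6)),
    truncnorm = {
      v <- stats::qnorm(u, median, max(iqr / (2 * z75), 0.25))
      pmin(pmax(v, lo), hi)
    },
    percent = {
      v <- stats::qnorm(u, median, max(iqr / (2 * z75), 0.25))
      pmin(pmax(v, lo), hi)
    },
    span = {
      v <- stats::qnorm(u, median, max(iqr / (2 * z75), 0.25))
      pmin(pmax(v, lo), hi)
    },
    count = {
      v <- round(stats::qnorm(u, median, max(iqr / (2 * z75), 0.5)))
      pmin(pmax(v, lo), hi)
    },
    stop("unknown calibration family: ", family)
  )
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-participant latent factor scores (temporal/cognitive,
#' dichotic/attention, peripheral hearing), maps them through each
#' measure's loading into a correlated standard-normal score, and converts
#' that score to measure units with the group's calibrated quantile map,
#' so each measure's marginal distribution matches its target median and
#' IQR in expectation while the planted factor structure links the
#' measures. The right ear advantage is derived as `total_r - total_l`
#' (the MCI deficit is carried by the left-ear score). Demographics (age,
#' education, gender) and MoCA are filled consistently with the group
#' definition (MCI: MoCA 19-25; control: 26-30).
#'
#' @param n_per_group participants per group (>= 2).
#' @param profile a [default_calibration()] data frame.
#' @param seed RNG seed.
#' @return A data frame of class `cohort_table`: one row per participant,
#'   with `id`, `group`, demographics, latent factor scores `f1`-`f3`, and
#'   one column per calibrated measure. Attributes `seed` and `profile`
#'   record provenance.
#' @export
generate_cohort <- function(n_per_group = 35, profile = default_calibration(),
                            seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  measures <- unique(profile$measure)
  for (m in measures) {
    g <- profile$group[profile$measure == m]
    if (!all(c("MCI", "control") %in% g))
      stop("calibration entry missing for measure '", m, "'")
  }
  n <- 2 * n_per_group
  group <- rep(c("MCI", "control"), each = n_per_group)
  with_seed(seed, {
    F <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("F1", "F2", "F3")))
    out <- data.frame(id = sprintf("P%03d", seq_len(n)), group = group,
                      gender = sample(c("female", "male"), n, replace = TRUE),
                      f1 = F[, 1], f2 = F[, 2], f3 = F[, 3],
                      stringsAsFactors = FALSE)
    for (m in measures) {
      val <- numeric(n)
      for (g in c("MCI", "control")) {
        row <- profile[profile$measure == m & profile$group == g, ]
        idx <- group == g
        lam <- row$loading
        z <- if (row$factor == "none" || lam == 0) {
          stats::rnorm(sum(idx))
        } else {
          lam * F[idx, row$factor] +
            sqrt(1 - lam^2) * stats::rnorm(sum(idx))
        }
        val[idx] <- calibration_quantile(stats::pnorm(z), row$median,
                                         row$iqr, row$family, row$lo, row$hi)
      }
      out[[m]] <- val
    }
    out$rea <- out$total_r - out$total_l
    attr(out, "seed") <- seed
    attr(out, "generator") <- paste0("capsim ",
      as.character(utils::packageVersion("capsim")))
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Virtual-listener parameters for one participant
#'
#' Deterministic monotone link from a participant's calibrated target
#' thresholds to the psychometric observers for the four adaptive tests:
#' the observer's threshold is set so that its 70.7%-correct point (the
#' 2-down-1-up convergence target) equals the participant's target value.
#' The two-interval interaural-phase test uses a chance rate of 1/2, the
#' three-interval tests 1/3.
#'
#' @param participant one cohort row (with `tfs_af`, `fmdl`, `attr`, `mdt`
#'   columns; `mdt` in dB).
#' @param slope,lapse psychometric spread (log10 units) and lapse rate.
#' @return Named list of [observer_model()] objects
#'   (`tfs_af`, `fmdl`, `attr`, `mdt`).
#' @export
observer_params_for <- function(participant, slope = 0.15, lapse = 0.02) {
  configs <- battery_staircase_configs()
  targets <- list(
    tfs_af = participant$tfs_af,
    fmdl = participant$fmdl,
    attr = participant$attr,
    mdt = 10^(participant$mdt / 20))
  out <- list()
  for (nm in names(targets)) {
    cfg <- configs[[nm]]
    guess <- if (nm == "tfs_af") 0.5 else 1 / 3
    x707 <- min(max(targets[[nm]], cfg$floor * 1.01), cfg$ceiling * 0.99)
    ref <- observer_model(1, slope = slope, guess = guess, lapse = lapse,
                          harder_direction = cfg$harder_direction)
    theta <- x707 / threshold_at_p(ref, 0.707)
    out[[nm]] <- observer_model(theta, slope = slope, guess = guess,
                                lapse = lapse,
                                harder_direction = cfg$harder_direction)
  }
  out
}

#' Run the adaptive battery for every cohort member
#'
#' Closed-loop simulation: each participant's four virtual listeners
#' answer their staircases and the estimated thresholds are written next
#' to the calibrated targets as `measured_tfs_af`, `measured_fmdl`,
#' `measured_attr`, `measured_mdt` (the last in dB). Tracks that end
#' without the full reversal quota yield `NA` and are flagged in
#' `measured_incomplete`.
#'
#' @param cohort a [generate_cohort()] table.
#' @param seed RNG seed (per-track seeds are derived from it).
#' @return The cohort with measured-threshold columns appended.
#' @export
simulate_measured_battery <- function(cohort, seed = 1) {
  configs <- battery_staircase_configs()
  tests <- names(configs)
  n <- nrow(cohort)
  seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max, n * length(tests)),
           n, length(tests), dimnames = list(NULL, tests)))
  res <- matrix(NA_real_, n, length(tests),
                dimnames = list(NULL, paste0("measured_", tests)))
  incomplete <- logical(n)
  for (i in seq_len(n)) {
    obs <- observer_params_for(cohort[i, ])
    for (j in seq_along(tests)) {
      tr <- run_track(configs[[tests[j]]], obs[[tests[j]]],
                      seed = seeds[i, j])
      res[i, j] <- tr$threshold
      if (!tr$complete) incomplete[i] <- TRUE
    }
  }
  out <- cbind(cohort, as.data.frame(res))
  out$measured_incomplete <- incomplete
  attr(out, "seed") <- attr(cohort, "seed")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#'
#' The CSV round-trips the full participant x measure schema; the
#' generator seed is stored in a `# seed:` comment line.
#'
#' @param cohort a `cohort_table`.
#' @param path CSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", attr(cohort, "seed") %||% "NA"), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1 else 0
  out <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  if (skip == 1 && grepl("# seed: [0-9]+", first))
    attr(out, "seed") <- as.integer(sub("# seed: ", "", first))
  class(out) <- c("cohort_table", "data.frame")
  out
}
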