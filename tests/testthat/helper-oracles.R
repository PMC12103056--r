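# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive-enumeration Mann-Whitney: null distribution of U over all
# C(n, n1) assignments of the pooled ranks; two-sided p as the doubled
# smaller tail, capped at 1.
enumerate_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Step-down Holm by the definition: sort ascending, running max of
# (m - j + 1) * p_(j), cap at 1, restore input order.
holm_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Analytic signal via FFT (hand-rolled Hilbert transform) and unwrapped
# instantaneous frequency in Hz.
instantaneous_frequency <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- ifelse(dph > pi, dph - 2 * pi, ifelse(dph < -pi, dph + 2 * pi, dph))
  dph * fs / (2 * pi)
}

# Least-squares AM-depth estimate from the squared signal: regression on
# sin/cos at the modulation rate and its double, then invert
# m = r (1 + m^2 / 2) with r = c_sin / (2 c_0).
fit_am_depth <- function(x, fs, rate_hz) {
  t <- (seq_along(x) - 1) / fs
  y <- x^2
  X <- cbind(sin(2 * pi * rate_hz * t), cos(2 * pi * rate_hz * t),
             sin(4 * pi * rate_hz * t), cos(4 * pi * rate_hz * t))
  fit <- stats::lm(y ~ X)
  c0 <- stats::coef(fit)[1]
  c1 <- sqrt(sum(stats::coef(fit)[2:3]^2))
  r <- unname(c1 / (2 * c0))
  (1 - sqrt(max(0, 1 - 2 * r^2))) / r
}

# Observer whose 70.7%-correct point sits at a requested stimulus value.
observer_at_x707 <- function(x707, config, slope = 0.15, lapse = 0.02) {
  guess <- if (config$name == "tfs_af") 0.5 else 1 / 3
  ref <- observer_model(1, slope = slope, guess = guess, lapse = lapse,
                        harder_direction = config$harder_direction)
  observer_model(x707 / threshold_at_p(ref, 0.707), slope = slope,
                 guess = guess, lapse = lapse,
                 harder_direction = config$harder_direction)
}

# Planted oblique/orthogonal factor model: R = L Phi L' + Psi with unit
# diagonal (loadings chosen so communalities < 1).
planted_factor_R <- function(L, Phi = NULL) {
  if (is.null(Phi)) Phi <- diag(ncol(L))
  R <- L %*% Phi %*% t(L)
  psi <- 1 - diag(R)
  R <- R + diag(psi)
  dimnames(R) <- list(rownames(L), rownames(L))
  R
}
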