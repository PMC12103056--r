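test_that("Bartlett's sphericity test gives textbook df and null value", {
  set.seed(5)
  R26 <- cor(matrix(rnorm(80 * 26), 80, 26))
  b26 <- bartlett_sphericity(R26, 80)
  expect_equal(b26$df, 325)                 # 26-variable input set
  R25 <- cor(matrix(rnorm(80 * 25), 80, 25))
  expect_equal(bartlett_sphericity(R25, 80)$df, 300)  # 25-variable set
  I5 <- diag(5)
  b0 <- bartlett_sphericity(I5, 50)
  expect_equal(b0$chisq, 0)
  expect_equal(b0$p, 1)
  expect_error(bartlett_sphericity(matrix(1:4, 2), 10), "symmetric")
})

test_that("KMO matches the closed form on an equicorrelation matrix", {
  p <- 3; rho <- 0.5
  R <- matrix(rho, p, p); diag(R) <- 1
  # closed-form inverse of the equicorrelation matrix
  denom <- 1 + (p - 1) * rho
  inv_off <- -(1 / (1 - rho)) * (rho / denom)
  inv_diag <- (1 / (1 - rho)) * (1 - rho / denom)
  q <- -inv_off / inv_diag
  n_off <- p * (p - 1) / 2
  kmo_hand <- (n_off * rho^2) / (n_off * rho^2 + n_off * q^2)
  expect_equal(kmo_overall(R), kmo_hand, tolerance = 1e-6)
  # invariant to variable reordering
  set.seed(2)
  R2 <- cor(matrix(rnorm(60 * 6), 60, 6))
  perm <- sample(6)
  expect_equal(kmo_overall(R2), kmo_overall(R2[perm, perm]),
               tolerance = 1e-12)
  expect_error(kmo_overall(diag(4)), "identity")
})

test_that("a single-factor correlation pattern has higher KMO than a block pattern", {
  R_single <- matrix(0.5, 4, 4); diag(R_single) <- 1
  R_block <- diag(4)
  R_block[1, 2] <- R_block[2, 1] <- 0.5
  R_block[3, 4] <- R_block[4, 3] <- 0.5
  expect_gt(kmo_overall(R_single), kmo_overall(R_block))
})

test_that("minres/oblimin recovers a planted 2-factor model from noiseless data", {
  L <- rbind(matrix(c(rep(0.8, 4), rep(0, 4)), 4, 2),
             matrix(c(rep(0, 4), rep(0.7, 4)), 4, 2))
  rownames(L) <- paste0("v", 1:8)
  R <- planted_factor_R(L)
  fit <- efa_fit(R, 2, n_obs = 200)
  cong <- aligned_congruence(fit$loadings, L)
  expect_true(all(cong > 0.98))
  # planted factors are orthogonal: recovered interfactor correlation small
  expect_lt(abs(fit$phi[1, 2]), 0.1)
  # model reconstruction: off-diagonal residuals below 1e-3
  model <- fit$loadings %*% fit$phi %*% t(fit$loadings)
  resid <- R - model
  diag(resid) <- 0
  expect_lt(max(abs(resid)), 1e-3)
  expect_length(fit$excluded, 0)
})

test_that("minres/oblimin recovers a planted 3-factor model and drops a noise variable", {
  L <- matrix(0, 10, 3)
  L[1:3, 1] <- c(0.85, 0.75, 0.7)
  L[4:6, 2] <- c(0.8, 0.7, 0.65)
  L[7:9, 3] <- c(0.75, 0.7, 0.8)
  # variable 10 loads on nothing: must fall to the 0.4 exclusion rule
  rownames(L) <- paste0("v", 1:10)
  R <- planted_factor_R(L)
  fit <- efa_fit(R, 3, n_obs = 300)
  expect_named(fit$excluded, "v10")
  expect_equal(sort(fit$retained), paste0("v", 1:9))
  cong <- aligned_congruence(fit$loadings, L[1:9, ])
  expect_true(all(cong > 0.98))
})

test_that("minres extraction agrees with maximum-likelihood factanal on clean data", {
  L <- rbind(matrix(c(rep(0.75, 5), rep(0, 5)), 5, 2),
             matrix(c(rep(0, 5), rep(0.65, 5)), 5, 2))
  rownames(L) <- paste0("v", 1:10)
  R <- planted_factor_R(L)
  ours <- minres_extract(R, 2)
  ml <- stats::factanal(covmat = R, factors = 2, n.obs = 500,
                        rotation = "none")
  cong <- aligned_congruence(unclass(ml$loadings), ours$loadings)
  expect_true(all(cong > 0.99))
})

test_that("oblique rotation recovers correlated planted factors", {
  L <- rbind(matrix(c(rep(0.8, 4), rep(0, 4)), 4, 2),
             matrix(c(rep(0, 4), rep(0.75, 4)), 4, 2))
  rownames(L) <- paste0("v", 1:8)
  Phi <- matrix(c(1, 0.4, 0.4, 1), 2)
  R <- planted_factor_R(L, Phi)
  fit <- efa_fit(R, 2, n_obs = 300)
  cong <- aligned_congruence(fit$loadings, L)
  expect_true(all(cong > 0.98))
  expect_equal(abs(fit$phi[1, 2]), 0.4, tolerance = 0.05)
})

test_that("efa_fit validates its inputs", {
  set.seed(9)
  X <- matrix(rnorm(50 * 6), 50, 6)
  expect_error(efa_fit(cor(X), 2), "n_obs")
  expect_error(minres_extract(cor(X), 6), "n_factors")
  fit <- efa_fit(as.data.frame(X), 2, loading_cutoff = 0)
  expect_equal(fit$n_obs, 50)
  expect_equal(fit$bartlett$df, 15)
})

test_that("parallel analysis counts planted factors on strong data", {
  set.seed(12)
  n <- 300
  F <- matrix(rnorm(n * 2), n, 2)
  X <- cbind(F[, 1] + 0.4 * matrix(rnorm(n * 3), n, 3),
             F[, 2] + 0.4 * matrix(rnorm(n * 3), n, 3))
  expect_equal(parallel_analysis(X, n_iter = 20, seed = 4), 2)
})
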