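test_that("Mann-Whitney matches enumeration on canonical cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  # identical multisets: U = n^2 / 2 and p near 1
  x <- c(1.2, 3.4, 5.6, 7.8)
  r2 <- mann_whitney_u(x, x)
  expect_equal(r2$U, length(x)^2 / 2)
  expect_gt(r2$p, 0.95)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("the normal approximation tracks enumeration on moderate samples", {
  set.seed(14)
  for (i in 1:20) {
    x <- round(rnorm(6), 6); y <- round(rnorm(6, 0.5), 6)
    exact <- enumerate_mw(x, y)
    approx <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                  correct = TRUE))
    expect_lt(abs(approx$p.value - exact$p), 0.02)
  }
})

test_that("Holm adjustment follows the step-down formula", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(2:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_by_hand(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("noncentral-t sample sizes reproduce the printed power analysis", {
  n <- power_n_per_group(0.8, 0.05, 0.90, tails = 1)
  expect_equal(n, 28L)
  expect_equal(2L * n, 56L)
  expect_equal(inflate_for_dropout(2L * n, 0.25), 70L)
  expect_equal(power_n_per_group(10, 0.05, 0.90, 1), 2L)
  expect_equal(inflate_for_dropout(56, 0), 56L)
})

test_that("sample sizes agree with power.t.test and the normal approximation", {
  grid <- expand.grid(d = c(0.4, 0.6, 0.8, 1.2), alpha = c(0.01, 0.05),
                      power = c(0.8, 0.9), tails = c(1, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    n <- power_n_per_group(g$d, g$alpha, g$power, g$tails)
    alt <- if (g$tails == 1) "one.sided" else "two.sided"
    ref <- ceiling(stats::power.t.test(delta = g$d, sd = 1,
                                       sig.level = g$alpha, power = g$power,
                                       alternative = alt)$n)
    expect_lte(abs(n - ref), 1)
    za <- qnorm(1 - g$alpha / g$tails); zb <- qnorm(g$power)
    n_norm <- ceiling(2 * ((za + zb) / g$d)^2)
    expect_lte(abs(n - n_norm), 2)
  }
})

test_that("sample size is monotone in effect size, alpha and power", {
  expect_gt(power_n_per_group(0.5, 0.05, 0.9, 1),
            power_n_per_group(0.8, 0.05, 0.9, 1))
  expect_gte(power_n_per_group(0.8, 0.01, 0.9, 1),
             power_n_per_group(0.8, 0.05, 0.9, 1))
  expect_gt(power_n_per_group(0.8, 0.05, 0.99, 1),
            power_n_per_group(0.8, 0.05, 0.9, 1))
  expect_error(inflate_for_dropout(56, 1), "rate")
  # inflation is even and never shrinks
  for (n in c(10, 11, 56)) {
    infl <- inflate_for_dropout(n, 0.25)
    expect_gte(infl, n)
    expect_equal(infl %% 2, 0)
  }
})

test_that("ROC analysis is fixed-direction and equals the U statistic", {
  set.seed(21)
  mci <- rnorm(30, 2); ctl <- rnorm(25)
  scores <- c(mci, ctl)
  labels <- rep(c("MCI", "control"), c(30, 25))
  r <- roc_analysis(scores, labels)
  u <- mann_whitney_u(mci, ctl)$U
  expect_equal(r$auc, u / (30 * 25), tolerance = 1e-12)
  # negation maps AUC to its complement (no auto-flipping)
  r_neg <- roc_analysis(-scores, labels)
  expect_equal(r_neg$auc, 1 - r$auc, tolerance = 1e-12)
  # perfect separation
  perf <- roc_analysis(c(rep(2, 5), rep(1, 5)), rep(c("MCI", "control"),
                                                    each = 5))
  expect_equal(perf$auc, 1)
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
  expect_error(roc_analysis(1:5, rep("MCI", 5)), "both classes")
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c("MCI", "control"), each = 40)
  ours <- roc_analysis(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c("control", "MCI"), direction = "<",
                   quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("regression reports the correct degrees of freedom and fits", {
  co <- generate_cohort(35, seed = 10)
  mci <- co[co$group == "MCI", ]
  m3 <- hierarchical_regression(mci, "moca",
                                c("fmdl", "attr", "mdt", "tfs_af"),
                                model_id = "temporal")
  expect_equal(m3$df1, 4)
  expect_equal(m3$df2, 30)
  expect_equal(m3$n, 35)
  expect_equal(m3$r_squared, m3$r^2, tolerance = 1e-12)
  # exact linear outcome: R^2 = 1
  d <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  d$y <- 2 + 3 * d$x1 - d$x2
  fit <- suppressWarnings(hierarchical_regression(d, "y", c("x1", "x2")))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # single predictor: standardized beta equals the Pearson correlation
  d2 <- data.frame(x = rnorm(50), e = rnorm(50))
  d2$y <- d2$x + d2$e
  f1 <- hierarchical_regression(d2, "y", "x")
  expect_equal(unname(f1$beta_std), cor(d2$y, d2$x), tolerance = 1e-12)
})

test_that("standardized betas are invariant to affine predictor rescaling", {
  set.seed(8)
  d <- data.frame(a = rnorm(40), b = rnorm(40))
  d$y <- d$a - 0.5 * d$b + rnorm(40, sd = 0.3)
  f0 <- hierarchical_regression(d, "y", c("a", "b"))
  d2 <- d
  d2$a <- 100 * d$a + 7
  f1 <- hierarchical_regression(d2, "y", c("a", "b"))
  expect_equal(unname(f0$beta_std), unname(f1$beta_std), tolerance = 1e-10)
  expect_equal(f0$r_squared, f1$r_squared, tolerance = 1e-12)
})
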