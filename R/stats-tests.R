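#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. Reports the
#' U statistic for the first sample. The p-value is exact (full
#' enumeration) for small tie-free samples (`n1 + n2 <= 12`) and otherwise
#' uses the normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples.
#' @return A list with `U`, `p`, `n1`, `n2`, and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y),
       method = if (exact) "exact" else "normal_approx")
}

#' Holm step-down multiplicity adjustment
#'
#' Adjusted p-values controlling the family-wise error rate: sort
#' ascending, take the running maximum of `(m - j + 1) * p_(j)`, cap at 1,
#' return in input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is an identity (no common factors):
#' `chi2 = -(n - 1 - (2p + 5) / 6) * ln |R|` on `p (p - 1) / 2` degrees of
#' freedom.
#'
#' @param R correlation matrix (symmetric, unit diagonal).
#' @param n sample size behind R.
#' @return A list with `chisq`, `df`, `p`.
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
      !isTRUE(all.equal(unname(diag(R)), rep(1, p), tolerance = 1e-8)))
    stop("R must be a symmetric correlation matrix with unit diagonal")
  detR <- det(R)
  if (detR <= 0) stop("R must be positive definite")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin sampling adequacy (overall)
#'
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal cells,
#' where `q_ij` are the anti-image partial correlations obtained from the
#' inverse correlation matrix.
#'
#' @param R correlation matrix (invertible, not the identity).
#' @return Overall KMO value in \[0, 1\].
#' @export
kmo_overall <- function(R) {
  p <- ncol(R)
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  if (r2 < .Machine$double.eps)
    stop("KMO is undefined for an identity correlation matrix")
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("KMO requires an invertible correlation matrix"))
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(d)   # partial correlations, sign-flipped inverse
  q2 <- sum(Q[off]^2)
  r2 / (r2 + q2)
}

#' Two-sample t-test sample size via the noncentral t distribution
#'
#' Smallest per-group n such that a two-sample t test with effect size d
#' attains the requested power: power is computed exactly from the
#' noncentral t with noncentrality `d * sqrt(n / 2)` on `2n - 2` degrees
#' of freedom.
#'
#' @param d Cohen's d effect size (> 0).
#' @param alpha significance level.
#' @param power target power (> alpha).
#' @param tails 1 or 2.
#' @return Integer n per group (>= 2).
#' @export
power_n_per_group <- function(d, alpha = 0.05, power = 0.90, tails = 1) {
  if (d <= 0) stop("effect size d must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= alpha || power >= 1) stop("power must lie in (alpha, 1)")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  attained <- function(n) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    crit <- stats::qt(1 - alpha / tails, df)
    pow <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
    if (tails == 2) pow <- pow + stats::pt(-crit, df, ncp = ncp)
    pow
  }
  for (n in 2:1e6) {
    if (attained(n) >= power) return(as.integer(n))
  }
  stop("requested power unattainable within n <= 1e6 per group")
}

#' Inflate a total sample size for expected dropout
#'
#' `ceil(total_n * (1 + rate))`, rounded up to an even total so the two
#' groups split equally.
#'
#' @param total_n total N over both groups.
#' @param rate expected dropout proportion in \[0, 1).
#' @return Inflated even total N.
#' @export
inflate_for_dropout <- function(total_n, rate) {
  if (rate < 0 || rate >= 1) stop("dropout rate must lie in [0, 1)")
  n <- ceiling(total_n * (1 + rate))
  if (n %% 2 == 1) n <- n + 1
  as.integer(n)
}

#' Empirical ROC analysis of a clinical measure
#'
#' Builds the empirical ROC over all observed score thresholds with the
#' fixed convention that higher scores predict the positive class
#' (no automatic direction flipping, so a measure on which positives score
#' lower yields AUC < 0.5). AUC is the trapezoidal area, equal to the
#' midrank Mann-Whitney `U / (n1 n2)`. The operating point maximizes
#' Youden's J = sensitivity + specificity - 1.
#'
#' @param scores numeric measure values.
#' @param labels class labels.
#' @param positive the positive-class label (e.g. `"MCI"`).
#' @return A list with `auc`, `threshold` (score at the Youden-optimal
#'   point; predicted positive when score >= threshold), `sensitivity` and
#'   `specificity` (percent), and the full `curve` data frame.
#' @export
roc_analysis <- function(scores, labels, positive = "MCI") {
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present (positive = '", positive, "')")
  n1 <- sum(pos); n0 <- sum(!pos)
  # operating points: predict positive when score >= t, over unique scores
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), sensitivity = c(0, sens),
                      fpr = c(0, 1 - spec))
  # midrank AUC (ties count half) = U / (n1 n0)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  j <- sens + spec - 1
  best <- which.max(j)
  list(auc = auc, threshold = thr[best],
       sensitivity = 100 * sens[best], specificity = 100 * spec[best],
       youden_j = j[best], curve = curve)
}

#' Ordinary least squares with standardized coefficients
#'
#' Fits `outcome ~ predictors` by OLS and reports estimates, standard
#' errors, standardized betas (from z-scored outcome and predictors),
#' t and p per predictor, plus R, R-squared and the overall F test on
#' `(k, n - k - 1)` degrees of freedom. A warning is attached (fit still
#' returned) when the predictor matrix is ill-conditioned.
#'
#' @param data data frame holding outcome and predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param model_id optional identifier echoed into the result.
#' @return A list of class `capsim_regression`.
#' @export
hierarchical_regression <- function(data, outcome, predictors,
                                    model_id = NULL) {
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data[, c(outcome, predictors)]
  df <- df[stats::complete.cases(df), ]
  n <- nrow(df); k <- length(predictors)
  form <- stats::as.formula(
    paste(outcome, "~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)
  X <- as.matrix(df[predictors])
  cond <- kappa(cbind(1, scale(X)), exact = TRUE)
  warning_msg <- if (is.finite(cond) && cond > 1e8)
    sprintf("ill-conditioned predictor matrix (condition number %.3g)", cond)
  else NULL
  # standardized betas: slope * sd(x) / sd(y)
  sds <- apply(X, 2, stats::sd)
  beta_std <- stats::coef(fit)[predictors] * sds / stats::sd(df[[outcome]])
  fstat <- sm$fstatistic
  coefs <- sm$coefficients
  structure(
    list(model_id = model_id,
         n = n,
         predictors = predictors,
         estimate = stats::coef(fit),
         se = coefs[, "Std. Error"],
         beta_std = beta_std,
         t = coefs[, "t value"],
         p = coefs[, "Pr(>|t|)"],
         r = sqrt(sm$r.squared),
         r_squared = sm$r.squared,
         f = unname(fstat["value"]),
         df1 = unname(fstat["numdf"]),
         df2 = unname(fstat["dendf"]),
         p_overall = stats::pf(fstat["value"], fstat["numdf"],
                               fstat["dendf"], lower.tail = FALSE),
         warning = warning_msg,
         fit = fit),
    class = "capsim_regression"
  )
}

#' @export
print.capsim_regression <- function(x, ...) {
  cat(sprintf("Model %s: R = %.3f, R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$model_id %||% "", x$r, x$r_squared, x$df1, x$df2, x$f,
              x$p_overall))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
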