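#' Exploratory factor analysis: minimum residual extraction with oblimin
#' rotation
#'
#' Implements the EFA stage used on the cohort measures: minres (ULS)
#' extraction minimizing the off-diagonal residuals of
#' `R - Lambda Lambda' - Psi`, followed by direct-quartimin (oblimin with
#' gamma = 0) oblique rotation via the gradient projection algorithm, a
#' single 0.4-loading exclusion pass, and the KMO / Bartlett adequacy
#' statistics on the retained variable set.
#'
#' @name efa
NULL

# squared multiple correlations (initial communality estimates)
smc <- function(R) {
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv)) return(rep(0.5, ncol(R)))
  pmin(pmax(1 - 1 / diag(Rinv), 0.05), 0.95)
}

# loadings from the reduced correlation matrix for given uniquenesses
loadings_from_psi <- function(R, psi, n_factors) {
  Rs <- R
  diag(Rs) <- 1 - psi
  e <- eigen(Rs, symmetric = TRUE)
  lam <- sqrt(pmax(e$values[seq_len(n_factors)], 0))
  L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(lam, n_factors)
  rownames(L) <- rownames(R)
  L
}

# minres objective: off-diagonal residual sum of squares
minres_objective <- function(psi, R, n_factors) {
  L <- loadings_from_psi(R, psi, n_factors)
  resid <- R - tcrossprod(L)
  diag(resid) <- 0
  sum(resid^2)
}

#' Minimum-residual (ULS) factor extraction
#'
#' @param R correlation matrix.
#' @param n_factors number of factors (>= 1, < number of variables).
#' @return A list with unrotated `loadings`, `uniqueness`, objective value
#'   and convergence info. Heywood uniquenesses are clipped at 0.005 with
#'   a warning.
#' @export
minres_extract <- function(R, n_factors) {
  p <- ncol(R)
  if (n_factors < 1 || n_factors >= p)
    stop("n_factors must lie in [1, ", p - 1, "]")
  psi0 <- 1 - smc(R)
  opt <- stats::optim(psi0, minres_objective, R = R, n_factors = n_factors,
                      method = "L-BFGS-B",
                      lower = rep(0.005, p), upper = rep(1, p),
                      control = list(maxit = 1000, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("minres extraction did not converge (optim code ", opt$convergence,
         " after ", opt$counts[1], " evaluations)")
  psi <- opt$par
  heywood <- psi <= 0.005 + 1e-12
  if (any(heywood))
    warning("Heywood case: uniqueness clipped to 0.005 for ",
            paste(colnames(R)[heywood], collapse = ", "))
  L <- loadings_from_psi(R, psi, n_factors)
  colnames(L) <- paste0("F", seq_len(n_factors))
  list(loadings = L, uniqueness = stats::setNames(psi, colnames(R)),
       objective = opt$value, converged = TRUE)
}

# quartimin criterion and gradient (oblimin family, gamma = 0)
quartimin_vgQ <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  M <- L2 %*% N
  list(f = sum(L2 * M) / 4, Gq = L * M)
}

#' Oblique quartimin (oblimin, gamma = 0) rotation
#'
#' Gradient projection algorithm for oblique rotation of a factor loading
#' matrix. Deterministic: starts from the identity plus a fixed set of
#' seeded random starts, keeping the solution with the lowest criterion.
#'
#' @param A unrotated loading matrix (variables x factors).
#' @param n_starts number of additional random starts.
#' @param max_iter,tol GPA iteration cap and gradient tolerance.
#' @return A list with the rotated pattern matrix `loadings`, the factor
#'   correlation matrix `phi`, the rotation matrix and the criterion value.
#' @export
rotate_oblimin <- function(A, n_starts = 4, max_iter = 500, tol = 1e-6) {
  k <- ncol(A)
  if (k == 1) return(list(loadings = A, phi = matrix(1, 1, 1),
                          rotation = matrix(1, 1, 1), criterion = 0))
  gpa_oblq <- function(Tmat) {
    al <- 1
    Ti <- solve(Tmat)
    L <- A %*% t(Ti)
    vg <- quartimin_vgQ(L)
    f <- vg$f
    G <- -t(t(L) %*% vg$Gq %*% Ti)
    for (iter in seq_len(max_iter)) {
      Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
      s <- sqrt(sum(Gp^2))
      if (s < tol) break
      al <- 2 * al
      for (h in 1:20) {
        X <- Tmat - al * Gp
        Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
        Ti <- solve(Tt)
        L <- A %*% t(Ti)
        vg <- quartimin_vgQ(L)
        if (vg$f < f - 0.5 * s^2 * al) break
        al <- al / 2
      }
      Tmat <- Tt
      f <- vg$f
      G <- -t(t(L) %*% vg$Gq %*% Ti)
    }
    list(loadings = L, phi = crossprod(Tmat), rotation = Tmat, criterion = f)
  }
  starts <- list(diag(k))
  rs <- with_seed(20201L, lapply(seq_len(n_starts), function(i) {
    M <- matrix(stats::rnorm(k * k), k, k)
    M %*% diag(1 / sqrt(colSums(M^2)), k)
  }))
  starts <- c(starts, rs)
  fits <- lapply(starts, gpa_oblq)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "criterion"))]]
  # sign convention: dominant loading of each factor positive
  L <- best$loadings
  flip <- vapply(seq_len(k), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  L <- L %*% diag(flip, k)
  phi <- diag(flip, k) %*% best$phi %*% diag(flip, k)
  dimnames(L) <- dimnames(A)
  dimnames(phi) <- list(colnames(A), colnames(A))
  list(loadings = L, phi = phi,
       rotation = best$rotation %*% diag(flip, k), criterion = best$criterion)
}

#' Fit an exploratory factor model
#'
#' Full EFA pipeline: correlation matrix, minres extraction, oblimin
#' rotation, then one exclusion pass dropping every variable whose maximum
#' absolute pattern loading falls below `loading_cutoff` and refitting on
#' the retained set. KMO and Bartlett's sphericity test are reported for
#' the retained variables.
#'
#' @param x data frame / matrix of observations, or a correlation matrix
#'   (square, symmetric, unit diagonal); in the latter case `n_obs` must
#'   be supplied for Bartlett's test.
#' @param n_factors number of factors to extract.
#' @param n_obs number of observations (required when `x` is a
#'   correlation matrix).
#' @param loading_cutoff exclusion threshold on the maximum absolute
#'   pattern loading (0 disables exclusion).
#' @param rotation `"oblimin"` or `"none"`.
#' @return An object of class `efa_result`: `loadings` (pattern matrix),
#'   `uniqueness`, `phi`, `cumulative_variance` (from squared pattern
#'   loadings), `kmo`, `bartlett`, `excluded` (named character vector of
#'   reasons), `retained`, `n_factors`, `n_obs`.
#' @export
efa_fit <- function(x, n_factors, n_obs = NULL, loading_cutoff = 0.4,
                    rotation = c("oblimin", "none")) {
  rotation <- match.arg(rotation)
  is_corr <- is.matrix(x) && nrow(x) == ncol(x) &&
    isTRUE(all.equal(unname(diag(x)), rep(1, ncol(x)), tolerance = 1e-8)) &&
    isTRUE(all.equal(x, t(x), tolerance = 1e-8))
  if (is_corr) {
    if (is.null(n_obs))
      stop("n_obs is required when x is a correlation matrix")
    R <- x
    if (is.null(colnames(R)))
      colnames(R) <- rownames(R) <- paste0("V", seq_len(ncol(R)))
  } else {
    x <- as.data.frame(x)
    x <- x[stats::complete.cases(x), , drop = FALSE]
    n_obs <- nrow(x)
    R <- stats::cor(as.matrix(x))
  }
  fit_once <- function(R) {
    ex <- minres_extract(R, n_factors)
    rot <- if (rotation == "oblimin") rotate_oblimin(ex$loadings)
           else list(loadings = ex$loadings,
                     phi = diag(ncol(ex$loadings)))
    list(extract = ex, loadings = rot$loadings, phi = rot$phi)
  }
  f1 <- fit_once(R)
  max_load <- apply(abs(f1$loadings), 1, max)
  drop <- names(max_load)[max_load < loading_cutoff]
  excluded <- stats::setNames(
    rep(sprintf("max |loading| < %.2f", loading_cutoff), length(drop)), drop)
  retained <- setdiff(colnames(R), drop)
  if (length(drop) > 0) {
    if (length(retained) <= n_factors)
      stop("exclusion pass left too few variables (", length(retained),
           ") for ", n_factors, " factors")
    R <- R[retained, retained]
    f1 <- fit_once(R)
  }
  bart <- bartlett_sphericity(R, n_obs)
  kmo <- kmo_overall(R)
  cumvar <- sum(f1$loadings^2) / ncol(R)
  structure(
    list(loadings = f1$loadings,
         uniqueness = f1$extract$uniqueness,
         phi = f1$phi,
         cumulative_variance = cumvar,
         kmo = kmo,
         bartlett = bart,
         excluded = excluded,
         retained = retained,
         n_factors = n_factors,
         n_obs = n_obs),
    class = "efa_result"
  )
}

#' @export
print.efa_result <- function(x, ...) {
  cat(sprintf(
    "EFA (minres/oblimin): %d factors, %d variables retained, %d excluded\n",
    x$n_factors, length(x$retained), length(x$excluded)))
  cat(sprintf("  KMO = %.3f; Bartlett chi2(%d) = %.1f, p = %.3g\n",
              x$kmo, x$bartlett$df, x$bartlett$chisq, x$bartlett$p))
  cat(sprintf("  cumulative variance (pattern loadings) = %.1f%%\n",
              100 * x$cumulative_variance))
  invisible(x)
}

#' Tucker congruence between two loading matrices
#'
#' Column-by-column congruence matrix
#' `phi(a, b) = a . b / sqrt((a . a)(b . b))`.
#'
#' @param A,B loading matrices with equal row count.
#' @return `ncol(A)` x `ncol(B)` congruence matrix.
#' @export
factor_congruence <- function(A, B) {
  num <- crossprod(A, B)
  den <- tcrossprod(sqrt(colSums(A^2)), sqrt(colSums(B^2)))
  num / den
}

#' Best-match congruence after sign and permutation alignment
#'
#' Greedy matching of recovered factors to planted factors on absolute
#' Tucker congruence; returns the per-planted-factor congruence after
#' alignment.
#'
#' @param recovered,planted loading matrices with equal dimensions.
#' @return Numeric vector: aligned |congruence| per planted factor.
#' @export
aligned_congruence <- function(recovered, planted) {
  C <- abs(factor_congruence(planted, recovered))
  k <- ncol(planted)
  out <- numeric(k)
  used <- integer(0)
  for (step in seq_len(k)) {
    C_mask <- C
    C_mask[, used] <- -Inf
    ij <- which(C_mask == max(C_mask), arr.ind = TRUE)[1, ]
    out[ij[1]] <- C[ij[1], ij[2]]
    used <- c(used, ij[2])
    C[ij[1], ] <- -Inf
  }
  out
}

#' Parallel-analysis factor-count helper
#'
#' Compares observed eigenvalues of the correlation matrix to the 95th
#' percentile of eigenvalues from random normal data of the same shape.
#' Advisory only: the analysis stage takes its factor counts from
#' configuration.
#'
#' @param x data frame or matrix of observations.
#' @param n_iter number of random datasets.
#' @param quantile eigenvalue quantile used as the retention bar.
#' @param seed RNG seed.
#' @return Suggested number of factors.
#' @export
parallel_analysis <- function(x, n_iter = 50, quantile = 0.95, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  sim <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
            symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  bar <- apply(sim, 1, stats::quantile, probs = quantile)
  max(1L, sum(obs > bar))
}
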