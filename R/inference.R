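#' Pearson product-moment correlation with strict input checks
#'
#' Degenerate inputs (fewer than 3 observations, constant vectors, missing
#' values) raise errors rather than returning NaN sentinels.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector")
  }
  stats::cor(x, y)
}

#' Permutation test for an association statistic
#'
#' Generates a null distribution by shuffling the participant labels of `y`
#' (equivalently, the correspondence between paired observations) on each of
#' `n_iter` iterations and recomputing the statistic. The two-tailed p-value
#' is the proportion of the null distribution strictly larger in absolute
#' value than the observed statistic (ties do not count against the observed
#' value); `smooth = TRUE` switches to the add-one estimator
#' `(b + 1) / (n_iter + 1)`.
#'
#' The default statistic is the Pearson correlation, computed by a vectorised
#' path; any deterministic `function(x, y)` may be supplied instead.
#'
#' @param x,y Paired numeric vectors.
#' @param statistic `NULL` for Pearson correlation, or a function of (x, y).
#' @param n_iter Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param smooth Use add-one smoothing for the p-value (default `FALSE`).
#' @return A `permutation_result`: `observed_stat`, `null_stats`,
#'   `p_two_tailed`, `n_iter`, `seed`.
#' @export
permutation_test <- function(x, y, statistic = NULL, n_iter = 10000L,
                             seed = 1L, smooth = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (n_iter < 1L) stop("n_iter must be at least 1")
  n <- length(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(statistic)) {
    observed <- pearson_r(x, y)
    xs <- x - mean(x)
    ys <- y - mean(y)
    sx <- sqrt(sum(xs^2))
    sy <- sqrt(sum(ys^2))
    idx <- vapply(seq_len(n_iter), function(i) sample.int(n), integer(n))
    yp <- matrix(ys[idx], nrow = n)
    null_stats <- as.numeric(crossprod(xs, yp)) / (sx * sy)
  } else {
    if (!is.function(statistic)) stop("statistic must be NULL or a function")
    observed <- statistic(x, y)
    null_stats <- vapply(seq_len(n_iter),
                         function(i) statistic(x, y[sample.int(n)]),
                         numeric(1))
  }
  if (!is.finite(observed) || anyNA(null_stats)) {
    stop("statistic undefined on observed or permuted data")
  }
  b <- sum(abs(null_stats) > abs(observed))
  p <- if (smooth) (b + 1) / (n_iter + 1) else b / n_iter
  res <- list(observed_stat = observed, null_stats = null_stats,
              p_two_tailed = p, n_iter = n_iter, seed = seed)
  class(res) <- "permutation_result"
  res
}

#' Ordinary least squares fit with residual diagnostics and AIC
#'
#' Fits `y ~ X` by least squares (via `stats::lm.fit`) and records the
#' residuals, residual sum of squares, and the Gaussian profile-likelihood
#' AIC `n * log(RSS / n) + 2 * (k + 1)`, where `k` counts the estimated
#' coefficients and the `+ 1` counts the error-variance parameter.
#'
#' @param y Outcome vector.
#' @param X Regressors: numeric vector, matrix, or data.frame.
#' @param include_intercept Prepend an intercept column (default `TRUE`).
#' @return A `linear_fit`: `coefficients`, `residuals`, `fitted`, `rss`, `n`,
#'   `k`, `aic`, plus the outcome and regressor names for nesting checks.
#' @export
ols_fit <- function(y, X, include_intercept = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != length(y)) stop("y and X must have matching rows")
  design <- if (include_intercept) {
    cbind("(Intercept)" = 1, X)
  } else X
  k <- ncol(design)
  n <- length(y)
  if (n <= k) stop("need more observations than coefficients")
  if (qr(design)$rank < k) stop("rank-deficient design matrix")
  fit <- stats::lm.fit(design, y)
  residuals <- as.numeric(fit$residuals)
  rss <- sum(residuals^2)
  if (rss <= 1e-12 * max(1, sum(y^2))) {
    stop("AIC undefined: residual sum of squares is zero (perfect fit)")
  }
  aic <- n * log(rss / n) + 2 * (k + 1)
  res <- list(coefficients = fit$coefficients, residuals = residuals,
              fitted = as.numeric(design %*% fit$coefficients),
              rss = rss, n = n, k = k, aic = aic,
              y = as.numeric(y), regressors = colnames(X),
              include_intercept = include_intercept)
  class(res) <- "linear_fit"
  res
}

#' Akaike evidence ratio between two models
#'
#' `exp(|AIC_a - AIC_b| / 2)`: the relative likelihood that the lower-AIC
#' model is the better model of the pair.
#'
#' @param aic_a,aic_b AIC values (finite).
#' @return An `evidence_ratio` list: `ratio` (>= 1), `favored` ("a", "b" or
#'   "tie"), and `delta_aic = aic_a - aic_b`.
#' @export
evidence_ratio <- function(aic_a, aic_b) {
  if (!is.finite(aic_a) || !is.finite(aic_b)) stop("AIC values must be finite")
  delta <- aic_a - aic_b
  res <- list(
    ratio = exp(abs(delta) / 2),
    favored = if (delta < 0) "a" else if (delta > 0) "b" else "tie",
    delta_aic = delta
  )
  class(res) <- "evidence_ratio"
  res
}

#' Nested-model F test with AIC evidence ratio
#'
#' Compares a reduced OLS model against a full model containing its
#' regressors plus extras, on the same outcome:
#' `F = ((RSS_r - RSS_f) / dk) / (RSS_f / (n - k_f))` with `(dk, n - k_f)`
#' degrees of freedom.
#'
#' @param reduced,full `linear_fit` objects from [ols_fit()].
#' @return A `model_comparison`: `f`, `df`, `p`, the two AICs, and the
#'   `evidence_ratio` in favor of the lower-AIC model.
#' @export
nested_f_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "linear_fit"), inherits(full, "linear_fit"))
  if (reduced$n != full$n || !isTRUE(all.equal(reduced$y, full$y))) {
    stop("models must be fit to the same outcome vector")
  }
  if (!all(reduced$regressors %in% full$regressors) ||
      reduced$k >= full$k ||
      reduced$include_intercept != full$include_intercept) {
    stop("models are not nested (reduced regressors must be a strict subset)")
  }
  dk <- full$k - reduced$k
  df2 <- full$n - full$k
  f <- ((reduced$rss - full$rss) / dk) / (full$rss / df2)
  er <- evidence_ratio(reduced$aic, full$aic)
  res <- list(
    f = f, df = c(dk, df2),
    p = stats::pf(f, dk, df2, lower.tail = FALSE),
    aic_reduced = reduced$aic, aic_full = full$aic,
    evidence_ratio = er$ratio,
    favored = c(a = "reduced", b = "full", tie = "tie")[[er$favored]]
  )
  class(res) <- "model_comparison"
  res
}

#' Split-half residual reliability (separability test)
#'
#' The headline procedure for asking whether towers-task performance carries
#' systematic individual variation beyond spatial and working-memory
#' abilities: (1) split the towers trials into stratified halves; (2) compute
#' each participant's towers accuracy on each half; (3) regress each half's
#' accuracy on the combined spatial and combined working-memory predictors
#' (computed once from the full data of the other four tasks, which are never
#' split); (4) correlate the two residual vectors; (5) assess significance by
#' permuting the participant correspondence between the residual vectors.
#' A significant positive residual correlation indicates reliable variance
#' the covariates cannot explain.
#'
#' @param trials Trial table (screened cohort).
#' @param scores `score_matrix` from [score_primary()], carrying the combined
#'   predictor columns.
#' @param seed Integer seed (split plan and permutations).
#' @param n_iter_perm Permutation iterations (default 10000).
#' @return A `residual_reliability` list: `r_resid`, `p_perm`, the two
#'   `linear_fit`s, and the `split_plan` used.
#' @export
residual_separability <- function(trials, scores, seed, n_iter_perm = 10000L) {
  stopifnot(inherits(scores, "score_matrix") ||
              all(c("participant_id", "combined_spatial", "combined_wm")
                  %in% names(scores)))
  plan <- stratified_split(trials, "towers", seed)
  halves <- half_accuracies(trials, plan,
                            participants = scores$participant_id)
  X <- cbind(combined_spatial = scores$combined_spatial,
             combined_wm = scores$combined_wm)
  fit_a <- ols_fit(halves$A, X)
  fit_b <- ols_fit(halves$B, X)
  r_resid <- pearson_r(fit_a$residuals, fit_b$residuals)
  perm <- permutation_test(fit_a$residuals, fit_b$residuals,
                           n_iter = n_iter_perm, seed = seed + 1L)
  res <- list(r_resid = r_resid, p_perm = perm$p_two_tailed,
              fit_a = fit_a, fit_b = fit_b, plan = plan,
              n_iter = n_iter_perm, seed = seed)
  class(res) <- "residual_reliability"
  res
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Nested model comparison: F(%d,%d) = %.2f, p = %.3g\n",
              x$df[1], x$df[2], x$f, x$p))
  cat(sprintf("  AIC reduced = %.2f, full = %.2f; the %s model is %.1f times more likely\n",
              x$aic_reduced, x$aic_full, x$favored, x$evidence_ratio))
  invisible(x)
}

#' @export
print.residual_reliability <- function(x, ...) {
  cat(sprintf("Residual split-half reliability: r = %.3f, permutation p = %.4g (%d iterations)\n",
              x$r_resid, x$p_perm, x$n_iter))
  invisible(x)
}
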