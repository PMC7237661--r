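test_that("pearson_r matches the hand covariance oracle and rejects degenerates", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  # hand oracle: sum(dx dy) / sqrt(sum dx^2 sum dy^2) = 8 / 10
  expect_equal(pearson_r(x, y), 0.8)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  expect_error(pearson_r(x, y[1:4]), "equal length")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration at n = 5", {
  x <- c(0.3, 1.2, -0.7, 2.1, 0.05)
  y <- c(1.1, -0.4, 0.9, 2.5, -1.3)
  obs <- cor(x, y)
  perms <- all_perms(5L)
  null_exact <- apply(perms, 2L, function(p) cor(x, y[p]))
  p_exact <- mean(abs(null_exact) > abs(obs))

  res <- permutation_test(x, y, n_iter = 20000L, seed = 9L)
  expect_equal(res$observed_stat, obs)
  se <- sqrt(p_exact * (1 - p_exact) / res$n_iter)
  expect_lt(abs(res$p_two_tailed - p_exact), 3 * se)

  # the custom-statistic path agrees with the vectorised Pearson path
  res2 <- permutation_test(x, y, statistic = function(a, b) cor(a, b),
                           n_iter = 2000L, seed = 9L)
  res3 <- permutation_test(x, y, n_iter = 2000L, seed = 9L)
  expect_equal(res2$p_two_tailed, res3$p_two_tailed)
  expect_equal(res2$null_stats, res3$null_stats, tolerance = 1e-12)

  # degenerate statistic propagates as an error
  expect_error(permutation_test(x, rep(1, 5), n_iter = 10L, seed = 1L))
})

test_that("ols_fit matches the normal equations and keeps residuals orthogonal", {
  # 4-point toy, hand oracle via normal equations: slope 0.6, intercept 1.1
  fit <- ols_fit(c(1, 2, 2, 3), c(0, 1, 2, 3))
  expect_equal(unname(fit$coefficients), c(1.1, 0.6), tolerance = 1e-10)
  expect_equal(fit$rss, 0.2, tolerance = 1e-10)

  set.seed(101)
  X <- matrix(rnorm(120), 40, 3)
  y <- 0.5 + X %*% c(1, -2, 0.3) + rnorm(40)
  fit <- ols_fit(y, X)
  D <- cbind(1, X)
  beta_ne <- solve(crossprod(D), crossprod(D, y))   # independent oracle
  expect_equal(unname(fit$coefficients), as.numeric(beta_ne),
               tolerance = 1e-10)
  for (j in seq_len(ncol(D))) {
    expect_lt(abs(sum(fit$residuals * D[, j])),
              1e-8 * sqrt(sum(y^2)) * sqrt(sum(D[, j]^2)))
  }
  expect_equal(fit$aic, fit$n * log(fit$rss / fit$n) + 2 * (fit$k + 1))

  # intercept-only: coefficient is the mean, RSS the total sum of squares
  fit0 <- ols_fit(as.numeric(y), matrix(numeric(0), 40, 0))
  expect_equal(unname(fit0$coefficients), mean(y))
  expect_equal(fit0$rss, sum((y - mean(y))^2))

  expect_error(ols_fit(c(1, 2, 3, 4), c(1, 2, 3, 4)), "zero")   # perfect fit
  expect_error(ols_fit(y, cbind(X, X[, 1])), "rank-deficient")
})

test_that("evidence ratios favor the lower-AIC model and tie at equality", {
  er <- evidence_ratio(-10, -8)
  expect_equal(er$ratio, exp(1))
  expect_equal(er$favored, "a")
  expect_equal(evidence_ratio(3, 1)$favored, "b")
  expect_equal(evidence_ratio(2, 2)$ratio, 1)
  expect_equal(evidence_ratio(2, 2)$favored, "tie")
  expect_error(evidence_ratio(NA, 1), "finite")
})

test_that("nested F test matches anova() and stays consistent with AIC", {
  set.seed(202)
  n <- 60L
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 0.8 * x1 + 0.3 * x2 + rnorm(n)
  reduced <- ols_fit(y, cbind(x1 = x1))
  full <- ols_fit(y, cbind(x1 = x1, x2 = x2))
  cmp <- nested_f_test(reduced, full)

  # independent oracle: R's anova on the same nesting
  av <- anova(lm(y ~ x1), lm(y ~ x1 + x2))
  expect_equal(cmp$f, av$F[2], tolerance = 1e-10)
  expect_equal(cmp$p, av$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(cmp$df, c(1L, n - 3L))
  expect_gte(cmp$evidence_ratio, 1)

  # AIC difference is an exact function of F: the sign flips exactly where
  # n * log(1 + dk * F / df2) crosses 2 * dk
  for (s in 1:25) {
    set.seed(300 + s)
    yy <- 1 + 0.8 * x1 + runif(1, 0, 0.5) * x2 + rnorm(n)
    r <- ols_fit(yy, cbind(x1 = x1))
    f <- ols_fit(yy, cbind(x1 = x1, x2 = x2))
    c2 <- nested_f_test(r, f)
    dk <- 1L; df2 <- n - 3L
    expect_equal(f$aic - r$aic,
                 -n * log(1 + dk * c2$f / df2) + 2 * dk, tolerance = 1e-10)
  }

  expect_error(nested_f_test(full, reduced), "not nested")
  expect_error(nested_f_test(ols_fit(rev(y), cbind(x1 = x1)), full),
               "same outcome")
})

test_that("residual separability recovers a planted physics-unique factor", {
  loadings <- c(0, 0.4, 0.8)
  mean_r <- vapply(seq_along(loadings), function(li) {
    rs <- vapply(1:5, function(rep) {
      cfg <- default_config(n_participants = 150L, loading_u = loadings[li],
                            seed = 1000L + 10L * li + rep)
      co <- simulate_cohort(cfg)
      scores <- score_primary(co$trials, cfg$schedule)
      res <- residual_separability(co$trials, scores, seed = 50L + rep,
                                   n_iter_perm = 200L)
      # residuals orthogonal to their own design, including the intercept
      X <- cbind(1, scores$combined_spatial, scores$combined_wm)
      for (j in 1:3) {
        expect_lt(abs(sum(res$fit_a$residuals * X[, j])), 1e-6)
      }
      res$r_resid
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  # expected residual reliability increases with the unique loading
  expect_lt(mean_r[1], mean_r[2])
  expect_lt(mean_r[2], mean_r[3])
  expect_gt(mean_r[3], 0.3)
})
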