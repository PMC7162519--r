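test_that("eigenvalues equal the squared canonical correlations of the concentrated residuals", {
  for (seed in cointsim:::spawn_seeds(21, 5)) {
    s <- make_ci_series(n = 150, seed = seed)
    fit <- fit_vecm(s, lag_diffs = 1)
    # independent route: rebuild the two residual sets and use stats::cancor
    y <- as.matrix(s); n <- nrow(y); dy <- diff(y); idx <- 2:(n - 1)
    Z0 <- dy[idx, ]; Z1 <- y[idx, ]; Z2 <- cbind(1, dy[idx - 1, ])
    R0 <- stats::lm.fit(Z2, Z0)$residuals
    R1 <- stats::lm.fit(Z2, Z1)$residuals
    cc <- stats::cancor(R0, R1, xcenter = FALSE, ycenter = FALSE)$cor
    expect_equal(fit$eigenvalues, cc^2, tolerance = 1e-8)
  }
})

test_that("rescaling the second series scales beta0_hat by the inverse factor", {
  s <- make_ci_series(n = 300, seed = 13)
  b0 <- johansen_trace(s)$beta0_hat
  s2 <- bivariate_series(s$y1, 4 * s$y2)
  expect_equal(johansen_trace(s2)$beta0_hat, b0 / 4, tolerance = 1e-8)
})

test_that("a level shift common to both series leaves the trace statistics unchanged", {
  s <- make_ci_series(n = 250, seed = 14)
  t1 <- johansen_trace(s)$trace_stats
  s2 <- bivariate_series(s$y1 + 100, s$y2 + 100)
  t2 <- johansen_trace(s2)$trace_stats
  expect_equal(t1, t2, tolerance = 1e-6)
})

test_that("the estimated cointegrating parameter is consistent for the true -b1/b2", {
  s <- simulate_system(dgp_spec("CI1", n_obs = 5000, b1 = 0.4, b2 = 0.6, seed = 19))
  expect_lt(abs(johansen_trace(s)$beta0_hat - (-2 / 3)), 0.05)
})

test_that("trace statistics are ordered and eigenvalues lie in [0, 1)", {
  for (kind in c("I0", "I1", "CI1")) {
    s <- simulate_system(dgp_spec(kind, n_obs = 120, seed = 23))
    jt <- johansen_trace(s)
    expect_gte(jt$trace_stats[1], jt$trace_stats[2])
    expect_gte(jt$trace_stats[2], 0)
    expect_true(all(jt$eigenvalues >= 0 & jt$eigenvalues < 1))
    expect_gte(jt$eigenvalues[1], jt$eigenvalues[2])
  }
})

test_that("classification at large samples recovers each true system type", {
  for (kind in c("I0", "I1", "CI1")) {
    s <- simulate_system(dgp_spec(kind, n_obs = 2000, seed = 29))
    expect_equal(johansen_trace(s)$classification, kind)
  }
})

test_that("degenerate inputs raise explicit errors", {
  const <- bivariate_series(rep(3, 100), rep(5, 100))
  expect_error(johansen_trace(const), "degenerate|singular")
  s <- make_ci_series(n = 100, seed = 2)
  s <- inject_missing(s, missing_spec("regular", every_k = 4))
  expect_error(fit_vecm(s), "drop_missing")
  expect_error(fit_vecm(make_ci_series(n = 21, seed = 2)), "fewer than 20")
  expect_error(fit_vecm(make_ci_series(n = 100, seed = 2), lag_diffs = 0),
               "at least 1")
})

test_that("coef/residuals methods expose the VECM parameters", {
  s <- make_ci_series(n = 200, seed = 31)
  jt <- johansen_trace(s)
  cf <- coef(jt)
  expect_equal(cf$beta[1], 1)
  expect_equal(cf$beta[2], jt$beta0_hat)
  expect_equal(dim(residuals(jt)), c(jt$fit$T_eff, 2))
})
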