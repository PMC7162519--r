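test_that("spec validation enforces the admissible parameter space", {
  expect_error(dgp_spec("I0", beta1 = 1.2), "stationary")
  expect_error(dgp_spec("CI1", b1 = 1, b2 = 0), "b2 != 0")
  expect_error(dgp_spec("I0", n_obs = 5), "at least 10")
  expect_error(simulate_ar1(1.5, 100), "explosive")
})

test_that("true_beta0 follows the -b1/b2 rule for cointegrated systems only", {
  expect_equal(true_beta0(dgp_spec("CI1", b1 = 0.4, b2 = 0.6)), -2 / 3)
  expect_equal(true_beta0(dgp_spec("CI1", b1 = 1, b2 = 1)), -1)
  expect_equal(true_beta0(dgp_spec("I1")), 0)
  expect_equal(true_beta0(dgp_spec("I0")), 0)
})

test_that("generation is deterministic given spec and seed", {
  a <- simulate_system(dgp_spec("I0", n_obs = 150, seed = 11))
  b <- simulate_system(dgp_spec("I0", n_obs = 150, seed = 11))
  expect_identical(a$y1, b$y1)
  expect_identical(a$y2, b$y2)
  c1 <- simulate_system(dgp_spec("CI1", n_obs = 150, seed = 11))
  expect_false(identical(a$y1, c1$y1))
})

test_that("an AR(1) with beta = 0 is white noise and beta = -0.5 has matching lag-1 autocorrelation", {
  wn <- simulate_ar1(0, 10000, seed = 5)
  expect_lt(abs(series_acf(wn, 1)[2]), 3 / sqrt(10000))
  y <- simulate_ar1(-0.5, 10000, seed = 5)
  expect_lt(abs(series_acf(y, 1)[2] - (-0.5)), 0.03)
})

test_that("stationary systems have vanishing long-lag autocorrelations", {
  s <- simulate_system(dgp_spec("I0", n_obs = 5000, seed = 9))
  a <- series_acf(s$y1, 10)
  expect_true(all(abs(a[6:11]) < 3 / sqrt(5000)))
})

test_that("the cointegration identity y1 - (b1/b2) y2 = u1 - (b1/b2) u2 holds exactly", {
  for (b in list(c(1, 1), c(0.4, 0.6), c(2, -1.5))) {
    s <- simulate_system(dgp_spec("CI1", n_obs = 300, b1 = b[1], b2 = b[2], seed = 8))
    inn <- s$meta$innovations
    lhs <- s$y1 - (b[1] / b[2]) * s$y2
    rhs <- inn$u1 - (b[1] / b[2]) * inn$u2
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("random-walk variance grows linearly in t", {
  n <- 200
  reps <- t(vapply(cointsim:::spawn_seeds(101, 500),
                   function(s) cointsim:::with_seed(s, cumsum(rnorm(n))),
                   numeric(n)))
  v <- apply(reps, 2, var)
  slope <- coef(lm(v ~ seq_len(n)))[2]
  expect_lt(abs(slope - 1), 0.2)   # sigma^2 = 1
})

test_that("a pure random walk is rarely rejected by the ADF test", {
  rate <- rejection_rate(200, 77, function(s) {
    y <- simulate_ar1(1, 500, seed = s)
    adf_test(y)$p_value <= 0.05
  })
  expect_lte(rate, 0.10)
})

test_that("the stationary combination of a cointegrated system rejects the unit root", {
  rate <- rejection_rate(200, 78, function(s) {
    ser <- simulate_system(dgp_spec("CI1", n_obs = 2000, b1 = 1, b2 = 1, seed = s))
    adf_test(ser$y1 - ser$y2)$p_value <= 0.05
  })
  expect_gte(rate, 0.90)
})

test_that("CSV writer and reader round-trip a series including the missing mask", {
  s <- make_ci_series(n = 60, seed = 3)
  s <- inject_missing(s, missing_spec("regular", every_k = 5))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_series_csv(s, path)
  r <- read_series_csv(path)
  expect_equal(r$observed, s$observed)
  expect_equal(r$y1[r$observed], s$y1[s$observed], tolerance = 1e-12)
})
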