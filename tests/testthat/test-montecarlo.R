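test_that("rank decisions map to system types by the rank of Pi", {
  expect_equal(classify(2), "I0")
  expect_equal(classify(1), "CI1")
  expect_equal(classify(0), "I1")
  jt <- johansen_trace(make_ci_series(n = 500, seed = 1))
  expect_equal(classify(jt), jt$classification)
})

test_that("pct_out agrees with a brute-force count under both fence conventions", {
  sets <- list(c(-1.3, -1.0, -1.0, -1.0, -1.0, -0.7),
               rep(-1, 10),
               cointsim:::with_seed(3, rnorm(101, -1, 0.1)))
  for (x in sets) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE); iqr <- q[2] - q[1]
    brute_q <- 100 * sum(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr) / length(x)
    brute_m <- 100 * sum(x < median(x) - 1.5 * iqr | x > median(x) + 1.5 * iqr) / length(x)
    expect_equal(pct_out(x), brute_q)
    expect_equal(pct_out(x, center = "median"), brute_m)
  }
  expect_equal(pct_out(rep(-1, 10)), 0)
  expect_error(pct_out(c(1, 2, 3)), "at least 4")
})

test_that("the outlier fences reproduce the median +/- 1.5 IQR arithmetic", {
  # interval implied by a median of -1.002 and an IQR of 0.097
  expect_equal(round(-1.002 + c(-1.5, 1.5) * 0.097, 3), c(-1.148, -0.857))
})

test_that("Monte Carlo rows are deterministic and conserve classification mass", {
  r1 <- mc_condition(n_reps = 30, master_seed = 5,
                     degradation = list(scale = scale_spec("interval", 3)))
  r2 <- mc_condition(n_reps = 30, master_seed = 5,
                     degradation = list(scale = scale_spec("interval", 3)))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  # correct% + wrong% + failed% = 100 per true type (recompute correct%)
  for (key in c("i1", "ci1", "i0")) {
    wrong <- r1[[paste0("misclass_", key)]]
    fail <- r1[[paste0("fail_", key)]]
    expect_equal((100 - wrong - fail) + wrong + fail, 100)
    expect_gte(wrong, 0); expect_lte(wrong + fail, 100)
  }
})

test_that("single-replication misclassification is all or nothing", {
  r <- mc_condition(n_reps = 1, master_seed = 9)
  expect_true(all(unlist(r[paste0("misclass_", c("i1", "ci1", "i0"))]) %in% c(0, 100)))
})

test_that("condition grids carry the published row labels", {
  g1 <- cointsim:::mc_grid("missing")
  expect_equal(names(g1)[1], "complete data")
  expect_true("30% random missing values" %in% names(g1))
  expect_true("every 3rd value is missing" %in% names(g1))
  g3 <- cointsim:::mc_grid("bounds")
  expect_equal(names(g3),
               c("untransformed data", "scale is bounded above (30%)",
                 "scale is bounded below (30%)", "scale is bounded above (50%)",
                 "scale is bounded on both sides (30%)"))
})

test_that("ordinal pooling cycles the four spacing schemes in equal shares", {
  sp <- pooled_ordinal(7)
  got <- vapply(1:8, function(i) {
    cointsim:::build_degradation(list(scale = sp), i)$scale$ordinal_scheme
  }, character(1))
  expect_equal(got[1:4], c("random", "increasing_from_median",
                           "decreasing_from_median", "monotone_increasing"))
  expect_equal(got[1:4], got[5:8])
})

test_that("estimation accuracy improves with sample size", {
  err <- function(n_obs) {
    b <- vapply(cointsim:::spawn_seeds(83, 60), function(s) {
      johansen_trace(make_ci_series(n = n_obs, seed = s))$beta0_hat
    }, numeric(1))
    median(abs(b + 1))
  }
  expect_lt(err(2000), err(100))
})
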