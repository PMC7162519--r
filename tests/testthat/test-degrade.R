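test_that("interval scaling splits the range into equal-width monotone bins", {
  expect_equal(to_interval_scale(c(0, 1, 2, 3), points = 2), c(1L, 1L, 2L, 2L))
  # integer-spaced input with points = number of distinct values is a
  # rank-preserving relabeling 1..k
  x <- c(10, 14, 12, 16, 18)
  expect_equal(to_interval_scale(x, points = 5), c(1L, 3L, 2L, 4L, 5L))
  expect_warning(out <- to_interval_scale(rep(2, 10), points = 4), "constant")
  expect_true(all(out == 1L))
})

test_that("a fine interval scale preserves nearly all ordering information", {
  x <- cointsim:::with_seed(31, rnorm(10000))
  sc <- to_interval_scale(x, 10)
  expect_gte(cor(x, sc, method = "spearman"), 0.97)
})

test_that("scale maps never invert the order of two values", {
  seeds <- cointsim:::spawn_seeds(55, 20)
  schemes <- c("random", "increasing_from_median", "decreasing_from_median",
               "monotone_increasing")
  for (i in seq_along(seeds)) {
    x <- cointsim:::with_seed(seeds[i], cumsum(rnorm(200)))
    o <- order(x)
    for (k in c(3, 7, 10)) {
      expect_true(!is.unsorted(to_interval_scale(x, k)[o]))
      sp <- scale_spec("ordinal", k, ordinal_scheme = schemes[(i - 1) %% 4 + 1],
                       seed = seeds[i])
      cat_x <- to_ordinal_scale(x, sp)
      expect_true(!is.unsorted(cat_x[o]))
      expect_lte(max(cat_x), k)
    }
  }
})

test_that("equal ordinal spacings reduce the ordinal map to the interval map", {
  x <- cointsim:::with_seed(7, rnorm(500))
  sp <- scale_spec("ordinal", 7, ordinal_scheme = "equal")
  expect_equal(to_ordinal_scale(x, sp), to_interval_scale(x, 7))
})

test_that("ordinal cut construction is deterministic given the scheme seed", {
  x <- cointsim:::with_seed(8, cumsum(rnorm(300)))
  sp <- scale_spec("ordinal", 5, ordinal_scheme = "random", seed = 99)
  expect_identical(to_ordinal_scale(x, sp), to_ordinal_scale(x, sp))
})

test_that("missing injection marks the prescribed occasions in both components", {
  s <- make_ci_series(n = 100, seed = 4)
  reg <- inject_missing(s, missing_spec("regular", every_k = 10))
  expect_equal(sum(!reg$observed), 10)
  rnd <- inject_missing(s, missing_spec("random", pct = 0.30, seed = 17))
  expect_equal(sum(!rnd$observed), 30)
  rnd2 <- inject_missing(s, missing_spec("random", pct = 0.30, seed = 17))
  expect_identical(rnd$observed, rnd2$observed)
  # observed values are untouched
  expect_identical(rnd$y1[rnd$observed], s$y1[rnd$observed])
  expect_error(inject_missing(make_ci_series(n = 30, seed = 4),
                              missing_spec("regular", every_k = 2)),
               "fewer than 20")
})

test_that("drop_missing closes the gaps and is the identity on complete data", {
  s <- make_ci_series(n = 100, seed = 4)
  expect_equal(as.matrix(drop_missing(s)), as.matrix(s))
  d <- drop_missing(inject_missing(s, missing_spec("random", pct = 0.30, seed = 1)))
  expect_equal(length(d$y1), 70)
  expect_true(all(d$observed))
})

test_that("bounding collapses marginal categories by observation fraction", {
  x <- rep(1:10, 10)
  above <- apply_bounds(x, bound_spec("above", 0.4))
  expect_equal(sort(unique(above)), 1:7)
  expect_equal(mean(above == 7), 0.4)
  below <- apply_bounds(x, bound_spec("below", 0.4))
  expect_equal(sort(unique(below)), 4:10)
  both <- apply_bounds(x, bound_spec("both", 0.3))
  expect_equal(sort(unique(both)), 2:9)
  # a tiny merged fraction only touches the extreme category: identity map
  expect_equal(apply_bounds(x, bound_spec("above", 0.01)), x)
  # monotone
  o <- order(x)
  expect_true(!is.unsorted(above[o]))
  # unreachable fraction stops at the median category with a warning
  expect_warning(apply_bounds(rep(5L, 50), bound_spec("above", 0.6)), "median")
})

test_that("degradation pipeline composes and records provenance", {
  s <- make_ci_series(n = 120, seed = 6)
  d <- degrade_system(s, scale = scale_spec("interval", 10),
                      bound = bound_spec("above", 0.3),
                      missing = missing_spec("random", pct = 0.1, seed = 2))
  expect_length(d$meta$transforms, 3)
  expect_true(all(d$y1[d$observed] >= 1 & d$y1[d$observed] <= 10))
  expect_equal(sum(!d$observed), 12)
})

test_that("the shared instrument is anchored on the pooled range of both series", {
  s <- bivariate_series(seq(0, 1, length.out = 50), seq(0, 100, length.out = 50))
  sc <- apply_scale(s, scale_spec("interval", 10))
  # y1 spans a hundredth of the pooled range: it occupies only the first category
  expect_true(all(sc$y1 == 1))
  expect_equal(sort(unique(sc$y2)), 1:10)
})
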