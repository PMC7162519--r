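# Monte Carlo harness: replication engine, quality indicators, and the
# standard condition grids (missing values, rating scales, bounded scales,
# sample-size sweep).

#' Map a rank decision to a system type
#'
#' Rank 2 means every linear combination is stationary (`I0`); rank 1 means
#' one equilibrium relation (`CI1`); rank 0 means integrated series without
#' a common trend (`I1`).
#'
#' @param result a `"johansen"` object, or a rank in 0:2.
#' @return `"I0"`, `"I1"` or `"CI1"`.
#' @export
classify <- function(result) {
  rank <- if (inherits(result, "johansen")) result$rank else result
  if (!rank %in% 0:2) stop("rank must be 0, 1 or 2", call. = FALSE)
  rank_to_class[rank + 1L]
}

#' Outlier rate of a collection of estimates
#'
#' Percentage of estimates falling strictly outside the 1.5-IQR fences.
#' With `center = "quartiles"` (the default, the convention used by the
#' replication tables) the fences are \eqn{[Q_1 - 1.5 IQR, Q_3 + 1.5 IQR]};
#' with `center = "median"` the interval is
#' \eqn{[median - 1.5 IQR, median + 1.5 IQR]}.
#'
#' @param estimates numeric vector (at least 4 values; `NA`s dropped).
#' @param center `"quartiles"` or `"median"`.
#' @return Percentage in \[0, 100\].
#' @export
pct_out <- function(estimates, center = c("quartiles", "median")) {
  center <- match.arg(center)
  x <- estimates[is.finite(estimates)]
  if (length(x) < 4) stop("at least 4 estimates required", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fence <- if (center == "quartiles") c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
           else stats::median(x) + c(-1.5, 1.5) * iqr
  100 * mean(x < fence[1] | x > fence[2])
}

# default generating specs for the three system types
default_dgp <- function(kind, n_obs) {
  switch(kind,
    I0  = dgp_spec("I0", n_obs = n_obs),
    I1  = dgp_spec("I1", n_obs = n_obs),
    CI1 = dgp_spec("CI1", n_obs = n_obs))
}

# per-replication degradation builder; scheme pooling cycles through the
# four ordinal spacing schemes in equal proportions
build_degradation <- function(degradation, rep_index) {
  d <- degradation
  if (!is.null(d$scale) && identical(d$scale$kind, "ordinal") &&
      identical(d$scale$ordinal_scheme, "pooled")) {
    schemes <- c("random", "increasing_from_median",
                 "decreasing_from_median", "monotone_increasing")
    d$scale <- scale_spec("ordinal", d$scale$points,
                          ordinal_scheme = schemes[(rep_index - 1L) %% 4L + 1L])
  }
  d
}

#' Run one Monte Carlo condition
#'
#' For each requested true system type, simulates `n_reps` systems of
#' intended length `n_obs`, pushes each through the degradation pipeline
#' (discretize/bound, inject missing, delete), runs the sequential trace
#' test at `level`, and scores:
#'
#' * `misclass_i1`, `misclass_ci1`, `misclass_i0` — percentage of
#'   replications (out of `n_reps`) whose estimated type differs from the
#'   true one;
#' * `mean`, `median`, `iqr`, `pct_out` — accuracy summaries of the
#'   normalized cointegrating-parameter estimates over the CI(1)
#'   replications, recorded from the leading eigenvector regardless of the
#'   rank decision;
#' * `fail_*` — percentage of replications whose fit was degenerate (these
#'   are excluded from the decision counts and estimates but reported, so
#'   correct% + wrong% + failed% = 100 per type).
#'
#' The run is deterministic given `master_seed`: one sub-seed is spawned
#' per replication.
#'
#' @param n_reps replications per system type (default 1000).
#' @param n_obs intended series length (default 100).
#' @param level significance level of the trace test (default 0.01).
#' @param degradation list with optional entries `scale` ([scale_spec()];
#'   an ordinal spec with `ordinal_scheme = "pooled"` cycles the four
#'   spacing schemes in equal shares), `bound` ([bound_spec()]), `missing`
#'   ([missing_spec()]) and `round_whole` (logical).
#' @param types true system types to simulate (default all three).
#' @param dgp optional named list of [dgp_spec()] templates overriding the
#'   defaults per type (their `n_obs` is overridden by `n_obs`).
#' @param lag_diffs lagged differences in the VECM (default 1).
#' @param master_seed master seed (required).
#' @return A one-row `data.frame` of class `"mc_row"`.
#' @examples
#' mc_condition(n_reps = 20, master_seed = 1, types = "CI1")
#' @export
mc_condition <- function(n_reps = 1000, n_obs = 100, level = 0.01,
                         degradation = list(), types = c("I1", "CI1", "I0"),
                         dgp = NULL, lag_diffs = 1, master_seed) {
  stopifnot(n_reps >= 1)
  types <- match.arg(types, c("I1", "CI1", "I0"), several.ok = TRUE)
  seeds <- matrix(spawn_seeds(master_seed, n_reps * 3L), ncol = 3L,
                  dimnames = list(NULL, c("I1", "CI1", "I0")))
  out <- list(misclass_i1 = NA_real_, misclass_ci1 = NA_real_,
              misclass_i0 = NA_real_, mean = NA_real_, median = NA_real_,
              iqr = NA_real_, pct_out = NA_real_,
              fail_i1 = NA_real_, fail_ci1 = NA_real_, fail_i0 = NA_real_)
  beta0_all <- NULL
  for (kind in types) {
    spec <- if (!is.null(dgp[[kind]])) dgp[[kind]] else default_dgp(kind, n_obs)
    spec$n_obs <- as.integer(n_obs)
    wrong <- 0L; failed <- 0L
    beta0 <- rep(NA_real_, n_reps)
    for (i in seq_len(n_reps)) {
      res <- with_seed(seeds[i, kind], {
        s <- simulate_system(spec, seed = NULL)
        d <- build_degradation(degradation, i)
        s <- degrade_system(s, scale = d$scale, bound = d$bound,
                            missing = d$missing,
                            round_whole = isTRUE(d$round_whole))
        s <- drop_missing(s)
        tryCatch(johansen_trace(s, lag_diffs = lag_diffs, level = level),
                 error = function(e) NULL)
      })
      if (is.null(res)) { failed <- failed + 1L; next }
      if (res$classification != kind) wrong <- wrong + 1L
      if (kind == "CI1") beta0[i] <- res$beta0_hat
    }
    key <- tolower(kind)
    out[[paste0("misclass_", key)]] <- 100 * wrong / n_reps
    out[[paste0("fail_", key)]] <- 100 * failed / n_reps
    if (kind == "CI1") beta0_all <- beta0[is.finite(beta0)]
  }
  if (!is.null(beta0_all) && length(beta0_all) >= 4) {
    out$mean <- mean(beta0_all)
    out$median <- stats::median(beta0_all)
    out$iqr <- stats::IQR(beta0_all)
    out$pct_out <- pct_out(beta0_all)
  }
  row <- as.data.frame(out)
  attr(row, "beta0") <- beta0_all
  attr(row, "config") <- list(n_reps = n_reps, n_obs = n_obs, level = level,
                              degradation = degradation, types = types,
                              lag_diffs = lag_diffs, master_seed = master_seed)
  class(row) <- c("mc_row", class(row))
  row
}

#' @export
print.mc_row <- function(x, ...) {
  print.data.frame(round(as.data.frame(x), 3))
  invisible(x)
}

#' Sample-size sweep of test performance
#'
#' Runs [mc_condition()] (no degradation) at each requested series length
#' and reports per-type and total misclassification plus the dispersion of
#' the cointegrating-parameter estimates.
#'
#' @param n_obs_values series lengths (each at least 10).
#' @param n_reps replications per type and length.
#' @param level significance level.
#' @param master_seed master seed; each length gets its own spawned seed.
#' @return A `data.frame` with one row per length, including
#'   `misclass_total` (simple mean over the three types, in percent).
#' @export
mc_sweep <- function(n_obs_values = c(30, 50, 70, 100, 200, 500),
                     n_reps = 500, level = 0.01, master_seed) {
  stopifnot(all(n_obs_values >= 10))
  seeds <- spawn_seeds(master_seed, length(n_obs_values))
  rows <- lapply(seq_along(n_obs_values), function(j) {
    r <- mc_condition(n_reps = n_reps, n_obs = n_obs_values[j], level = level,
                      master_seed = seeds[j])
    data.frame(n_obs = n_obs_values[j],
               misclass_i1 = r$misclass_i1, misclass_ci1 = r$misclass_ci1,
               misclass_i0 = r$misclass_i0,
               misclass_total = mean(c(r$misclass_i1, r$misclass_ci1,
                                       r$misclass_i0)),
               median = r$median, iqr = r$iqr, pct_out = r$pct_out)
  })
  do.call(rbind, rows)
}

# named degradation lists for the standard condition grids
mc_grid <- function(which) {
  switch(which,
    missing = list(
      "complete data" = list(round_whole = TRUE),
      "every 10th value is missing" = list(round_whole = TRUE,
        missing = missing_spec("regular", every_k = 10)),
      "every 7th value is missing" = list(round_whole = TRUE,
        missing = missing_spec("regular", every_k = 7)),
      "every 5th value is missing" = list(round_whole = TRUE,
        missing = missing_spec("regular", every_k = 5)),
      "every 3rd value is missing" = list(round_whole = TRUE,
        missing = missing_spec("regular", every_k = 3)),
      "10% random missing values" = list(round_whole = TRUE,
        missing = missing_spec("random", pct = 0.10)),
      "14% random missing values" = list(round_whole = TRUE,
        missing = missing_spec("random", pct = 0.14)),
      "20% random missing values" = list(round_whole = TRUE,
        missing = missing_spec("random", pct = 0.20)),
      "30% random missing values" = list(round_whole = TRUE,
        missing = missing_spec("random", pct = 0.30))),
    scales = list(
      "continuous data" = list(),
      "10-point interval scale" = list(scale = scale_spec("interval", 10)),
      "7-point interval scale" = list(scale = scale_spec("interval", 7)),
      "5-point interval scale" = list(scale = scale_spec("interval", 5)),
      "3-point interval scale" = list(scale = scale_spec("interval", 3)),
      "7-point ordinal scale" = list(scale = pooled_ordinal(7)),
      "10-point ordinal scale" = list(scale = pooled_ordinal(10))),
    bounds = list(
      "untransformed data" = list(),
      "scale is bounded above (30%)" = list(scale = scale_spec("interval", 10),
        bound = bound_spec("above", 0.30)),
      "scale is bounded below (30%)" = list(scale = scale_spec("interval", 10),
        bound = bound_spec("below", 0.30)),
      "scale is bounded above (50%)" = list(scale = scale_spec("interval", 10),
        bound = bound_spec("above", 0.50)),
      "scale is bounded on both sides (30%)" = list(scale = scale_spec("interval", 10),
        bound = bound_spec("both", 0.30))),
    stop("unknown grid: ", which, call. = FALSE)
  )
}

#' Ordinal scale spec pooling the four spacing schemes
#'
#' A [scale_spec()] whose scheme is resolved per replication by
#' [mc_condition()], cycling through random / increasing-from-median /
#' decreasing-from-median / monotone-increasing in equal shares.
#'
#' @param points number of scale points.
#' @return A `"scale_spec"` with `ordinal_scheme = "pooled"`.
#' @export
pooled_ordinal <- function(points) {
  sp <- scale_spec("ordinal", points, ordinal_scheme = "random")
  sp$ordinal_scheme <- "pooled"
  sp
}

#' Reproduce a standard condition grid
#'
#' Runs the full grid of degradation conditions for one of the three
#' replication studies — missing values (`"missing"`), levels of
#' measurement (`"scales"`), ceiling/floor effects (`"bounds"`) — or the
#' sample-size sweep (`"sweep"`), all at the default study conditions
#' (T = 100, 1 percent level, \eqn{\beta_0 = -1}).
#'
#' @param which `"missing"`, `"scales"`, `"bounds"` or `"sweep"`.
#' @param n_reps replications per condition and type.
#' @param master_seed master seed; each grid row gets its own spawned seed.
#' @param ... further arguments passed to [mc_condition()] / [mc_sweep()].
#' @return A `data.frame`, one labelled row per condition.
#' @export
reproduce_table <- function(which = c("missing", "scales", "bounds", "sweep"),
                            n_reps = 1000, master_seed, ...) {
  which <- match.arg(which)
  if (which == "sweep") {
    return(mc_sweep(n_reps = max(n_reps %/% 2, 1), master_seed = master_seed, ...))
  }
  grid <- mc_grid(which)
  seeds <- spawn_seeds(master_seed, length(grid))
  rows <- lapply(seq_along(grid), function(j) {
    r <- mc_condition(n_reps = n_reps, degradation = grid[[j]],
                      master_seed = seeds[j], ...)
    cbind(condition = names(grid)[j], as.data.frame(r))
  })
  do.call(rbind, rows)
}
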