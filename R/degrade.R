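# Psychometric degradation operators: rating-scale discretization, missing
# measurement occasions, and ceiling/floor (bounded-scale) effects.

#' Specify a rating scale
#'
#' @param kind `"interval"` (equal category widths) or `"ordinal"` (unequal
#'   widths following `ordinal_scheme`).
#' @param points number of scale points, 3 to 10.
#' @param ordinal_scheme how consecutive category widths vary (ordinal
#'   only): `"random"` draws widths i.i.d. uniform(0.5, 1.5);
#'   `"increasing_from_median"` / `"decreasing_from_median"` grow/shrink
#'   widths geometrically (ratio 1.5) outward from the scale midpoint;
#'   `"monotone_increasing"` uses a geometric width sequence (ratio 1.3)
#'   left to right; `"equal"` reduces the ordinal construction to the
#'   interval one.
#' @param seed seed used by the `"random"` scheme.
#' @return An object of class `"scale_spec"`.
#' @export
scale_spec <- function(kind = c("interval", "ordinal"), points = 10,
                       ordinal_scheme = c("random", "increasing_from_median",
                                          "decreasing_from_median",
                                          "monotone_increasing", "equal"),
                       seed = NULL) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(points, "points")
  if (points < 3 || points > 10) stop("`points` must lie in 3..10", call. = FALSE)
  spec <- list(kind = kind, points = as.integer(points), seed = seed)
  if (kind == "ordinal") spec$ordinal_scheme <- match.arg(ordinal_scheme)
  structure(spec, class = "scale_spec")
}

#' Specify a missing-data pattern
#'
#' @param mode `"regular"` (every k-th occasion fails) or `"random"` (a
#'   simple random sample of occasions fails).
#' @param every_k spacing of failing occasions (regular mode, `>= 2`).
#' @param pct fraction of occasions failing (random mode, in (0, 0.5)).
#' @param seed seed for the random mode.
#' @return An object of class `"missing_spec"`.
#' @export
missing_spec <- function(mode = c("regular", "random"), every_k = NULL,
                         pct = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "regular") {
    if (is.null(every_k) || !is.null(pct)) {
      stop("regular mode requires `every_k` and no `pct`", call. = FALSE)
    }
    stop_if_not_scalar_number(every_k, "every_k")
    if (every_k < 2) stop("`every_k` must be at least 2", call. = FALSE)
  } else {
    if (is.null(pct) || !is.null(every_k)) {
      stop("random mode requires `pct` and no `every_k`", call. = FALSE)
    }
    stop_if_not_scalar_number(pct, "pct")
    if (pct <= 0 || pct >= 0.5) stop("`pct` must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(mode = mode, every_k = every_k, pct = pct, seed = seed),
            class = "missing_spec")
}

#' Specify a bounded (ceiling/floor) scale
#'
#' @param side which end of a 10-point scale is limited: `"above"`,
#'   `"below"`, or `"both"`.
#' @param merged_fraction fraction of observations absorbed into the
#'   boundary category (in (0, 0.6]); for `side = "both"` it is split
#'   equally between the two tails.
#' @return An object of class `"bound_spec"`.
#' @export
bound_spec <- function(side = c("above", "below", "both"), merged_fraction = 0.3) {
  side <- match.arg(side)
  stop_if_not_scalar_number(merged_fraction, "merged_fraction")
  if (merged_fraction <= 0 || merged_fraction > 0.6) {
    stop("`merged_fraction` must lie in (0, 0.6]", call. = FALSE)
  }
  structure(list(side = side, merged_fraction = merged_fraction),
            class = "bound_spec")
}

#' Map a continuous sequence onto a k-point interval scale
#'
#' Partitions `range` into `points` equal-width half-open bins (the last
#' bin closed above) and maps each value to its bin index `1..points`. The
#' mapping is monotone non-decreasing. By default the bins are anchored on
#' the realized range of `x`; passing a wider `range` (e.g. the pooled
#' range of both variables of a system, as [apply_scale()] does) emulates a
#' single instrument shared across variables.
#'
#' @param x numeric sequence.
#' @param points number of scale points (`>= 2`).
#' @param range numeric length-2 anchor for the scale; defaults to
#'   `range(x)`.
#' @return Integer sequence of scale categories.
#' @examples
#' to_interval_scale(c(0, 1, 2, 3), points = 2)  # 1 1 2 2
#' @export
to_interval_scale <- function(x, points, range = base::range(x)) {
  stop_if_not_scalar_number(points, "points")
  if (points < 2) stop("`points` must be at least 2", call. = FALSE)
  if (range[1] >= range[2]) {
    warning("constant input: all values mapped to scale point 1")
    return(rep(1L, length(x)))
  }
  breaks <- seq(range[1], range[2], length.out = points + 1)
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

# Consecutive category widths for an ordinal scale (relative; rescaled by
# the caller to cover the anchor range).
ordinal_widths <- function(points, scheme) {
  switch(scheme,
    random = stats::runif(points, 0.5, 1.5),
    increasing_from_median = 1.5^(abs(seq_len(points) - (points + 1) / 2)),
    decreasing_from_median = 1.5^(-abs(seq_len(points) - (points + 1) / 2)),
    monotone_increasing = 1.3^(seq_len(points) - 1),
    equal = rep(1, points),
    stop("unknown ordinal scheme: ", scheme, call. = FALSE)
  )
}

#' Map a continuous sequence onto an ordinal scale with unequal spacings
#'
#' Builds `points - 1` interior cut points across `range` whose consecutive
#' spacings follow `spec$ordinal_scheme` (see [scale_spec()]), then assigns
#' each value its category `1..points`. The mapping is monotone; with equal
#' spacings it coincides with [to_interval_scale()].
#'
#' @param x numeric sequence.
#' @param spec a [scale_spec()] with `kind = "ordinal"`.
#' @param range numeric length-2 anchor for the scale; defaults to `range(x)`.
#' @return Integer sequence of scale categories.
#' @export
to_ordinal_scale <- function(x, spec, range = base::range(x)) {
  stopifnot(inherits(spec, "scale_spec"))
  if (spec$kind != "ordinal") stop("`spec` must be an ordinal scale_spec", call. = FALSE)
  if (range[1] >= range[2]) {
    warning("constant input: all values mapped to scale point 1")
    return(rep(1L, length(x)))
  }
  k <- spec$points
  w <- with_seed(spec$seed, ordinal_widths(k, spec$ordinal_scheme))
  w <- w / sum(w) * (range[2] - range[1])
  breaks <- range[1] + c(0, cumsum(w))
  breaks[k + 1] <- range[2]  # guard rounding drift at the top
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Discretize both variables of a system on one shared scale
#'
#' Applies a rating scale to both components of a bivariate series, with
#' the scale anchored on the pooled range of the two observed sequences —
#' one questionnaire spanning the whole phenomenon, administered to both
#' variables. The variable with the smaller dispersion therefore occupies
#' fewer categories, which is how unequal variances become consequential
#' on coarse scales.
#'
#' @param series a [bivariate_series()].
#' @param spec a [scale_spec()].
#' @return The series with both components replaced by scale categories.
#' @export
apply_scale <- function(series, spec) {
  stopifnot(inherits(series, "bivariate_series"), inherits(spec, "scale_spec"))
  obs <- series$observed
  pooled <- base::range(c(series$y1[obs], series$y2[obs]))
  f <- if (spec$kind == "interval") {
    function(x) to_interval_scale(x, spec$points, range = pooled)
  } else {
    function(x) to_ordinal_scale(x, spec, range = pooled)
  }
  series$y1 <- as.numeric(f(series$y1))
  series$y2 <- as.numeric(f(series$y2))
  series$meta$transforms <- c(series$meta$transforms,
                              sprintf("%d-point %s scale", spec$points, spec$kind))
  series
}

#' Round a system to whole-number values
#'
#' The mildest discreteness manipulation: every value is replaced by the
#' nearest integer, without imposing a bounded scale.
#'
#' @param series a [bivariate_series()].
#' @return The rounded series.
#' @export
round_whole <- function(series) {
  stopifnot(inherits(series, "bivariate_series"))
  series$y1 <- round(series$y1)
  series$y2 <- round(series$y2)
  series$meta$transforms <- c(series$meta$transforms, "rounded to whole numbers")
  series
}

#' Mark measurement occasions as missing
#'
#' Both components are unobserved at the same time points (a skipped
#' measurement occasion). `"regular"` mode marks every k-th index
#' (k, 2k, ...); `"random"` mode marks a simple random sample of
#' `floor(pct * n)` indices. Observed values are left bit-identical.
#'
#' @param series a [bivariate_series()].
#' @param spec a [missing_spec()].
#' @return The series with its `observed` mask updated.
#' @export
inject_missing <- function(series, spec) {
  stopifnot(inherits(series, "bivariate_series"), inherits(spec, "missing_spec"))
  n <- length(series$y1)
  drop_idx <- if (spec$mode == "regular") {
    seq(spec$every_k, n, by = spec$every_k)
  } else {
    with_seed(spec$seed, sort(sample.int(n, floor(spec$pct * n))))
  }
  observed <- series$observed
  observed[drop_idx] <- FALSE
  if (sum(observed) < 20) {
    stop("fewer than 20 observations would remain after injecting missing values",
         call. = FALSE)
  }
  series$observed <- observed
  series$meta$transforms <- c(series$meta$transforms,
    if (spec$mode == "regular") sprintf("every %dth value missing", spec$every_k)
    else sprintf("%.0f%% random missing", 100 * spec$pct))
  series
}

#' Drop unobserved occasions and close the gaps
#'
#' Listwise deletion: unobserved time points are removed and the remainder
#' concatenated into a contiguous series. Downstream tests then treat the
#' result as equidistant — precisely the distortion that missing values
#' inflict on real longitudinal data.
#'
#' @param series a [bivariate_series()].
#' @return A shorter, fully observed [bivariate_series()].
#' @export
drop_missing <- function(series) {
  stopifnot(inherits(series, "bivariate_series"))
  keep <- series$observed
  bivariate_series(series$y1[keep], series$y2[keep],
                   meta = c(series$meta, list(deleted = sum(!keep))))
}

# Collapse one tail of a 1..10 scale until the boundary category has
# absorbed at least `frac` of the observations. Collapse never crosses the
# category containing the median.
collapse_tail <- function(x, frac, upper = TRUE) {
  med <- stats::median(x)
  cats <- if (upper) 10:1 else 1:10
  for (m in cats) {
    reached <- if (upper) mean(x >= m) >= frac else mean(x <= m) >= frac
    at_median <- if (upper) m <= med else m >= med
    if (reached || at_median) {
      merged_any <- if (upper) any(x > m) else any(x < m)
      if (at_median && !merged_any) {
        warning("merged fraction unreachable (degenerate tail); collapse stopped at the median category")
      }
      return(if (upper) pmin(x, m) else pmax(x, m))
    }
  }
  x
}

#' Impose ceiling/floor effects on a 10-point scale
#'
#' Collapses marginal categories of a 10-point scale into a single boundary
#' category until the collapsed categories hold at least
#' `spec$merged_fraction` of the observations; `side = "both"` splits the
#' fraction equally between the two tails. The mapping is monotone. If the
#' target fraction cannot be reached the collapse stops at the category
#' containing the median, with a warning.
#'
#' @param x integer sequence with values in 1..10.
#' @param spec a [bound_spec()].
#' @return Integer sequence on the limited scale.
#' @examples
#' x <- rep(1:10, 10)
#' table(apply_bounds(x, bound_spec("above", 0.4)))  # 7..10 merged to 7
#' @export
apply_bounds <- function(x, spec) {
  stopifnot(inherits(spec, "bound_spec"))
  if (any(x < 1 | x > 10, na.rm = TRUE)) {
    stop("`x` must already lie on a 10-point scale (values 1..10)", call. = FALSE)
  }
  switch(spec$side,
    above = collapse_tail(x, spec$merged_fraction, upper = TRUE),
    below = collapse_tail(x, spec$merged_fraction, upper = FALSE),
    both  = collapse_tail(collapse_tail(x, spec$merged_fraction / 2, upper = TRUE),
                          spec$merged_fraction / 2, upper = FALSE)
  )
}

#' @describeIn apply_bounds apply the bounding to both components of a
#'   bivariate series (each component's own category frequencies decide
#'   where its collapse stops).
#' @param series a [bivariate_series()] whose components hold 10-point
#'   categories.
#' @export
apply_bounds_system <- function(series, spec) {
  stopifnot(inherits(series, "bivariate_series"))
  series$y1 <- as.numeric(apply_bounds(series$y1, spec))
  series$y2 <- as.numeric(apply_bounds(series$y2, spec))
  series$meta$transforms <- c(series$meta$transforms,
    sprintf("bounded %s (%.0f%%)", spec$side, 100 * spec$merged_fraction))
  series
}

#' Run a full degradation pipeline
#'
#' Applies, in order: rounding or scale discretization, bounding, missing
#' injection — mimicking how a bounded instrument is administered on some
#' measurement occasions. Deletion of the missing occasions is left to
#' [drop_missing()] so that callers can inspect the mask.
#'
#' @param series a [bivariate_series()].
#' @param scale optional [scale_spec()].
#' @param bound optional [bound_spec()] (requires a 10-point scale step).
#' @param missing optional [missing_spec()].
#' @param round_whole round to whole numbers instead of a bounded scale.
#' @return The degraded [bivariate_series()].
#' @export
degrade_system <- function(series, scale = NULL, bound = NULL, missing = NULL,
                           round_whole = FALSE) {
  stopifnot(inherits(series, "bivariate_series"))
  if (round_whole) series <- round_whole(series)
  if (!is.null(scale)) series <- apply_scale(series, scale)
  if (!is.null(bound)) series <- apply_bounds_system(series, bound)
  if (!is.null(missing)) series <- inject_missing(series, missing)
  series
}
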