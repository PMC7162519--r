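#' Specify a bivariate data-generating process
#'
#' Defines one of the three bivariate system types used throughout the
#' simulation studies, together with its parameters and the implied true
#' cointegrating parameter:
#'
#' * `"I0"` — a stationary system: two independent AR(1) processes
#'   \eqn{y_{i,t} = \beta_i y_{i,t-1} + u_{i,t}} with \eqn{|\beta_i| < 1}.
#' * `"I1"` — an integrated system without a common trend: each series loads
#'   on its *own* unit random walk, \eqn{y_{i,t} = b_i x_{i,t} + u_{i,t}}.
#'   Unequal loadings \eqn{b_1 \neq b_2} give the two series unequal
#'   variances. Setting `noise_sd = 0` reduces this to two pure random walks
#'   with innovation standard deviations `b1`, `b2`.
#' * `"CI1"` — a cointegrated system: both series share the *same* unit
#'   random walk \eqn{x_t}, \eqn{y_{i,t} = b_i x_t + u_{i,t}}, so the
#'   combination \eqn{y_1 - (b_1/b_2) y_2} is stationary and the
#'   cointegrating vector is \eqn{(1, \beta_0)'} with
#'   \eqn{\beta_0 = -b_1/b_2}.
#'
#' All innovations are i.i.d. standard normal unless scaled by the
#' parameters above; measurement noise \eqn{u_{i,t}} has standard deviation
#' `noise_sd`.
#'
#' @param kind system type, one of `"I0"`, `"I1"`, `"CI1"`.
#' @param n_obs intended series length (at least 10).
#' @param beta1,beta2 AR(1) coefficients for `"I0"` (both `< 1` in absolute
#'   value).
#' @param b1,b2 trend loadings for `"I1"`/`"CI1"`; `b2` must be non-zero for
#'   `"CI1"`.
#' @param noise_sd standard deviation of the white measurement noise added
#'   on top of the trend component(s) for `"I1"`/`"CI1"`.
#' @param burn_in initialization values discarded before the sample starts;
#'   applies to the stationary components only (random walks start at 0).
#' @param seed optional integer seed stored with the spec and used by
#'   [simulate_system()] when no seed is passed there.
#'
#' @return An object of class `"dgp_spec"`.
#' @seealso [simulate_system()], [true_beta0()]
#' @examples
#' spec <- dgp_spec("CI1", n_obs = 100, b1 = 0.4, b2 = 0.6, seed = 1)
#' true_beta0(spec)   # -0.667
#' @export
dgp_spec <- function(kind = c("I0", "I1", "CI1"), n_obs = 100,
                     beta1 = -0.5, beta2 = -0.2,
                     b1 = NULL, b2 = NULL, noise_sd = 1,
                     burn_in = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(n_obs, "n_obs")
  if (n_obs < 10) stop("`n_obs` must be at least 10", call. = FALSE)
  if (kind == "I0") {
    stop_if_not_scalar_number(beta1, "beta1")
    stop_if_not_scalar_number(beta2, "beta2")
    if (abs(beta1) >= 1 || abs(beta2) >= 1) {
      stop("stationary systems require |beta1| < 1 and |beta2| < 1", call. = FALSE)
    }
    params <- list(beta1 = beta1, beta2 = beta2)
    burn_in <- burn_in %||% 50L
  } else {
    # loading defaults: CI(1) uses the beta0 = -1 parameterization; I(1) uses
    # unequal loadings so the two series have unequal variances
    if (kind == "CI1") { b1 <- b1 %||% 1; b2 <- b2 %||% 1 }
    else               { b1 <- b1 %||% 0.8; b2 <- b2 %||% 1.2 }
    stop_if_not_scalar_number(b1, "b1")
    stop_if_not_scalar_number(b2, "b2")
    stop_if_not_scalar_number(noise_sd, "noise_sd")
    if (kind == "CI1" && b2 == 0) {
      stop("cointegrated systems require b2 != 0 so that beta0 = -b1/b2 is finite",
           call. = FALSE)
    }
    if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
    params <- list(b1 = b1, b2 = b2, noise_sd = noise_sd)
    burn_in <- burn_in %||% 0L
  }
  stop_if_not_scalar_number(burn_in, "burn_in")
  if (burn_in < 0) stop("`burn_in` must be non-negative", call. = FALSE)
  structure(
    list(kind = kind, n_obs = as.integer(n_obs), params = params,
         burn_in = as.integer(burn_in), seed = seed),
    class = "dgp_spec"
  )
}

#' @export
print.dgp_spec <- function(x, ...) {
  cat(sprintf("Bivariate DGP spec: %s system, n_obs = %d, burn_in = %d\n",
              x$kind, x$n_obs, x$burn_in))
  cat("  parameters:",
      paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "), "\n")
  if (x$kind == "CI1") cat(sprintf("  true beta0 = %.4f\n", true_beta0(x)))
  invisible(x)
}

#' True cointegrating parameter of a specified system
#'
#' For cointegrated systems the long-run equilibrium is
#' \eqn{y_1 = \beta_0 y_2} with \eqn{\beta_0 = -b_1/b_2}; stationary and
#' integrated systems have no equilibrium relation and score
#' \eqn{\beta_0 = 0}.
#'
#' @param spec a [dgp_spec()] object.
#' @return The true \eqn{\beta_0} as a number.
#' @export
true_beta0 <- function(spec) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (spec$kind == "CI1") -spec$params$b1 / spec$params$b2 else 0
}

#' Simulate a first-order autoregression
#'
#' Generates \eqn{y_t = \beta y_{t-1} + u_t} with i.i.d. standard-normal
#' innovations, starting from 0 and discarding `burn_in` initial values.
#' `beta = 1` gives a pure random walk; `beta = 0` white noise. Explosive
#' processes (`|beta| > 1`) are rejected.
#'
#' @param beta autoregressive coefficient, `|beta| <= 1`.
#' @param n_obs number of values returned.
#' @param seed optional integer seed.
#' @param burn_in initial values discarded (default 0).
#' @return Numeric vector of length `n_obs`.
#' @examples
#' y <- simulate_ar1(-0.5, 200, seed = 1)
#' @export
simulate_ar1 <- function(beta, n_obs, seed = NULL, burn_in = 0) {
  stop_if_not_scalar_number(beta, "beta")
  if (abs(beta) > 1) stop("explosive processes (|beta| > 1) are not supported",
                          call. = FALSE)
  stop_if_not_scalar_number(n_obs, "n_obs")
  with_seed(seed, {
    u <- stats::rnorm(n_obs + burn_in)
    y <- if (beta == 0) u else as.numeric(stats::filter(u, beta, method = "recursive"))
    y[(burn_in + 1):(burn_in + n_obs)]
  })
}

#' Construct a bivariate series object
#'
#' The common payload passed between generators, degradation operators and
#' tests: two aligned numeric sequences plus an observation mask. Values at
#' positions with `observed = FALSE` are treated as absent by all consumers.
#'
#' @param y1,y2 numeric sequences of equal length.
#' @param observed logical mask of the same length (default all `TRUE`).
#' @param meta free-form provenance list (generating spec, transforms applied).
#' @return An object of class `"bivariate_series"`.
#' @export
bivariate_series <- function(y1, y2, observed = NULL, meta = list()) {
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  if (length(y1) != length(y2)) stop("y1 and y2 must have equal length", call. = FALSE)
  observed <- observed %||% rep(TRUE, length(y1))
  if (length(observed) != length(y1) || !is.logical(observed)) {
    stop("`observed` must be a logical mask matching the series length", call. = FALSE)
  }
  structure(list(y1 = y1, y2 = y2, observed = observed, meta = meta),
            class = "bivariate_series")
}

#' @export
print.bivariate_series <- function(x, ...) {
  cat(sprintf("Bivariate series: length %d, %d observed\n",
              length(x$y1), sum(x$observed)))
  if (!is.null(x$meta$spec)) cat("  generated from:", x$meta$spec$kind, "system\n")
  if (length(x$meta$transforms)) {
    cat("  transforms:", paste(x$meta$transforms, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.bivariate_series <- function(x, ...) {
  cbind(y1 = x$y1, y2 = x$y2)
}

#' @export
length.bivariate_series <- function(x) length(x$y1)

#' @export
plot.bivariate_series <- function(x, ...) {
  m <- as.matrix(x)
  m[!x$observed, ] <- NA
  graphics::matplot(m, type = "l", lty = 1, col = c("black", "grey50"),
                    xlab = "t", ylab = "value", ...)
  graphics::legend("topleft", legend = c("y1", "y2"), lty = 1,
                   col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Simulate a bivariate system from a DGP spec
#'
#' Draws one realization of the system described by `spec` (see
#' [dgp_spec()] for the three constructions). The generating innovations and
#' shared trend are recorded in `meta$innovations` so that algebraic
#' identities (for cointegrated systems,
#' \eqn{y_1 - (b_1/b_2) y_2 = u_1 - (b_1/b_2) u_2}) can be checked exactly.
#' Output is deterministic given the seed.
#'
#' @param spec a [dgp_spec()] object.
#' @param seed integer seed; defaults to the seed stored in the spec.
#' @return A [bivariate_series()] with all positions observed.
#' @examples
#' s <- simulate_system(dgp_spec("I0", n_obs = 200, seed = 7))
#' @export
simulate_system <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "dgp_spec"))
  n <- spec$n_obs
  p <- spec$params
  out <- with_seed(seed, {
    switch(spec$kind,
      I0 = {
        y1 <- simulate_ar1(p$beta1, n, burn_in = spec$burn_in)
        y2 <- simulate_ar1(p$beta2, n, burn_in = spec$burn_in)
        list(y1 = y1, y2 = y2, innov = NULL)
      },
      I1 = {
        x1 <- cumsum(stats::rnorm(n))
        x2 <- cumsum(stats::rnorm(n))
        u1 <- stats::rnorm(n, sd = p$noise_sd)
        u2 <- stats::rnorm(n, sd = p$noise_sd)
        list(y1 = p$b1 * x1 + u1, y2 = p$b2 * x2 + u2,
             innov = list(x1 = x1, x2 = x2, u1 = u1, u2 = u2))
      },
      CI1 = {
        x <- cumsum(stats::rnorm(n))
        u1 <- stats::rnorm(n, sd = p$noise_sd)
        u2 <- stats::rnorm(n, sd = p$noise_sd)
        list(y1 = p$b1 * x + u1, y2 = p$b2 * x + u2,
             innov = list(x = x, u1 = u1, u2 = u2))
      }
    )
  })
  bivariate_series(out$y1, out$y2,
                   meta = list(spec = spec, innovations = out$innov,
                               transforms = character()))
}

#' @rdname simulate_system
#' @param object a `"dgp_spec"` object (S3 `simulate` method).
#' @param nsim number of realizations; one returns a single
#'   [bivariate_series()], more a list of them.
#' @param ... unused.
#' @export
simulate.dgp_spec <- function(object, nsim = 1, seed = object$seed, ...) {
  if (nsim == 1) return(simulate_system(object, seed = seed))
  seeds <- spawn_seeds(seed %||% stop("`seed` required for nsim > 1"), nsim)
  lapply(seeds, function(s) simulate_system(object, seed = s))
}

#' Write a bivariate series to CSV
#'
#' Two columns `y1,y2`, one row per time point; unobserved values are
#' written as empty fields.
#'
#' @param series a [bivariate_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_series_csv()]
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "bivariate_series"))
  y1 <- ifelse(series$observed, format(series$y1, digits = 15, trim = TRUE), "")
  y2 <- ifelse(series$observed, format(series$y2, digits = 15, trim = TRUE), "")
  writeLines(c("y1,y2", paste(y1, y2, sep = ",")), con = path)
  invisible(path)
}
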