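# Maximum-likelihood cointegration rank test (trace variant) and VECM
# estimation for bivariate systems, via reduced-rank regression.

# Critical values of the trace statistic for a VECM with an unrestricted
# constant (data may carry stochastic or deterministic trends; no
# deterministic term inside the cointegrating relation). Rows indexed by
# the number of common trends under H0 (n - r), columns by level.
JO_TRACE_CV <- matrix(
  c(6.50,  8.18, 11.65,
    15.66, 17.95, 23.52),
  nrow = 2, byrow = TRUE,
  dimnames = list(c("1", "2"), c("10pct", "5pct", "1pct"))
)

#' Trace-test critical value
#'
#' Table lookup for the trace statistic of a bivariate VECM with an
#' unrestricted constant, e.g. `critical_value(2, 0.01)` is 23.52 and
#' `critical_value(1, 0.01)` is 11.65.
#'
#' @param n_minus_r number of common trends under the null (1 or 2).
#' @param level significance level: 0.10, 0.05 or 0.01.
#' @return The critical value.
#' @export
critical_value <- function(n_minus_r, level = 0.01) {
  if (!n_minus_r %in% c(1, 2)) stop("`n_minus_r` must be 1 or 2", call. = FALSE)
  col <- match(TRUE, abs(c(0.10, 0.05, 0.01) - level) < 1e-9)
  if (is.na(col)) stop("`level` must be one of 0.10, 0.05, 0.01", call. = FALSE)
  JO_TRACE_CV[as.character(n_minus_r), col]
}

# Sequential rank decision: test r = 0, then r <= 1; the estimated rank is
# the first hypothesis not rejected (2 if both are).
jo_rank_decision <- function(trace_stats, level = 0.01) {
  if (trace_stats[1] <= critical_value(2, level)) return(0L)
  if (trace_stats[2] <= critical_value(1, level)) return(1L)
  2L
}

rank_to_class <- c("I1", "CI1", "I0")  # index rank + 1

#' Fit a bivariate VECM by reduced-rank regression
#'
#' Concentrates the vector error correction model
#' \deqn{\Delta y_t = \Pi y_{t-1} + \Gamma_1 \Delta y_{t-1} + \dots +
#'   \Gamma_{K-1} \Delta y_{t-K+1} + c + u_t}
#' by regressing \eqn{\Delta y_t} and \eqn{y_{t-1}} on the lagged
#' differences and the constant, and solves the generalized eigenproblem
#' \eqn{|\lambda S_{11} - S_{10} S_{00}^{-1} S_{01}| = 0} of the residual
#' product-moment matrices. The eigenvalues are the squared canonical
#' correlations between the two residual sets; the eigenvectors are the
#' candidate cointegrating vectors.
#'
#' @param series a fully observed [bivariate_series()], or any object
#'   [as.matrix()] turns into a two-column numeric matrix.
#' @param lag_diffs number of lagged-difference terms (K - 1, at least 1).
#' @return A list of class `"vecm_fit"` with eigenvalues, `beta_raw`,
#'   `alpha`, `Gamma`, the S-matrices, residuals and `T_eff`.
#' @seealso [johansen_trace()] for the test built on this fit.
#' @export
fit_vecm <- function(series, lag_diffs = 1) {
  y <- as.matrix(series)
  if (inherits(series, "bivariate_series") && !all(series$observed)) {
    stop("series contains unobserved points; call drop_missing() first",
         call. = FALSE)
  }
  if (ncol(y) != 2) stop("a bivariate (two-column) system is required", call. = FALSE)
  stop_if_not_scalar_number(lag_diffs, "lag_diffs")
  if (lag_diffs < 1) stop("`lag_diffs` must be at least 1", call. = FALSE)
  lag_diffs <- as.integer(lag_diffs)
  n <- nrow(y)
  if (n - lag_diffs - 1 < 20) {
    stop("fewer than 20 usable rows after lagging", call. = FALSE)
  }
  dy <- diff(y)
  idx <- (lag_diffs + 1):(n - 1)            # rows t = lag_diffs + 2 .. n
  Z0 <- dy[idx, , drop = FALSE]             # Delta y_t
  Z1 <- y[idx, , drop = FALSE]              # y_{t-1} (transitory form)
  Z2 <- cbind(1, do.call(cbind, lapply(seq_len(lag_diffs),
                                       function(i) dy[idx - i, , drop = FALSE])))
  T_eff <- nrow(Z0)

  cp <- crossprod(Z2)
  ok <- is.finite(rcond(cp)) && rcond(cp) > 1e-14
  if (!ok) stop("degenerate input: short-run regressor matrix is singular",
                call. = FALSE)
  P <- solve(cp, t(Z2))
  R0 <- Z0 - Z2 %*% (P %*% Z0)
  R1 <- Z1 - Z2 %*% (P %*% Z1)
  S00 <- crossprod(R0) / T_eff
  S11 <- crossprod(R1) / T_eff
  S01 <- crossprod(R0, R1) / T_eff
  if (rcond(S00) < 1e-12 || rcond(S11) < 1e-12) {
    stop("degenerate input: residual product-moment matrix is (near) singular",
         call. = FALSE)
  }

  es <- eigen(S11, symmetric = TRUE)
  S11_isqrt <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  A <- S11_isqrt %*% t(S01) %*% solve(S00, S01) %*% S11_isqrt
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lambda <- pmin(pmax(ev$values, 0), 1 - 1e-12)
  beta_raw <- S11_isqrt %*% ev$vectors      # beta' S11 beta = I
  alpha <- S01 %*% beta_raw                 # = S01 beta (beta' S11 beta)^{-1}

  # short-run coefficients and residuals at full rank (diagnostic use)
  Pi_hat <- alpha %*% t(beta_raw)
  Gamma <- t(solve(cp, crossprod(Z2, Z0 - Z1 %*% t(Pi_hat))))
  resid <- Z0 - Z1 %*% t(Pi_hat) - Z2 %*% t(Gamma)

  structure(
    list(lag_diffs = lag_diffs, T_eff = T_eff,
         eigenvalues = lambda, beta_raw = beta_raw, alpha = alpha,
         S00 = S00, S01 = S01, S11 = S11,
         Gamma = Gamma, residuals = resid),
    class = "vecm_fit"
  )
}

#' @export
print.vecm_fit <- function(x, ...) {
  cat(sprintf("Bivariate VECM fit (reduced-rank regression), %d lagged difference(s), T_eff = %d\n",
              x$lag_diffs, x$T_eff))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Johansen trace test for a bivariate system
#'
#' Fits the VECM with [fit_vecm()] and performs the sequential
#' likelihood-ratio test of the rank of \eqn{\Pi}: the trace statistic for
#' H0 \eqn{r \le j} is \eqn{-T_{eff} \sum_{i > j} \log(1 - \lambda_i)}.
#' Rank 0 classifies the system as integrated without a common trend
#' (`I1`), rank 1 as cointegrated (`CI1`), rank 2 as stationary (`I0`).
#' The leading eigenvector, normalized to \eqn{(1, \beta_0)'}, estimates
#' the cointegrating vector; it is reported whatever the rank decision, so
#' inference and estimation quality can be scored separately.
#'
#' @param x a [bivariate_series()], a two-column matrix, or the `y1`
#'   vector when `y` is given.
#' @param y optional second series when `x` is a vector.
#' @param lag_diffs number of lagged-difference terms (default 1: the
#'   VAR(2)-equivalent minimal choice for first-order systems).
#' @param level significance level of the sequential decision (0.10, 0.05
#'   or 0.01; default 0.01).
#' @return An object of class `"johansen"`: eigenvalues, `trace_stats`,
#'   `crit_vals`, `rank`, `classification`, `beta0_hat`, `beta`, `alpha`,
#'   and the underlying `fit`. `beta0_hat` is `NA` when the leading
#'   eigenvector cannot be normalized (first component ~ 0).
#' @examples
#' s <- simulate_system(dgp_spec("CI1", n_obs = 200, b1 = 0.4, b2 = 0.6, seed = 1))
#' jt <- johansen_trace(s)
#' jt$rank        # 1
#' coef(jt)       # normalized cointegrating vector and loadings
#' @export
johansen_trace <- function(x, y = NULL, lag_diffs = 1, level = 0.01) {
  series <- if (!is.null(y)) cbind(y1 = x, y2 = y) else x
  fit <- fit_vecm(series, lag_diffs = lag_diffs)
  trace_test(fit, level = level)
}

#' Trace statistics and rank decision from a fitted VECM
#'
#' @param fit a `"vecm_fit"` from [fit_vecm()].
#' @param level significance level (0.10, 0.05 or 0.01).
#' @return An object of class `"johansen"`; see [johansen_trace()].
#' @export
trace_test <- function(fit, level = 0.01) {
  stopifnot(inherits(fit, "vecm_fit"))
  lambda <- fit$eigenvalues
  stats <- c("r = 0"  = -fit$T_eff * sum(log(1 - lambda)),
             "r <= 1" = -fit$T_eff * log(1 - lambda[2]))
  rank <- jo_rank_decision(stats, level)
  b <- fit$beta_raw[, 1]
  beta0 <- if (abs(b[1]) < 1e-10) NA_real_ else b[2] / b[1]
  structure(
    list(trace_stats = stats,
         crit_vals = JO_TRACE_CV,
         level = level,
         rank = rank,
         classification = rank_to_class[rank + 1L],
         eigenvalues = lambda,
         beta0_hat = beta0,
         beta = if (is.na(beta0)) c(1, NA_real_) else c(1, beta0),
         alpha = fit$alpha,
         fit = fit),
    class = "johansen"
  )
}

#' @export
print.johansen <- function(x, ...) {
  cat("Johansen trace test (bivariate VECM, unrestricted constant)\n\n")
  cv <- x$crit_vals[c("2", "1"), ]
  tab <- cbind(statistic = round(x$trace_stats, 2), round(cv, 2))
  rownames(tab) <- names(x$trace_stats)
  print(tab)
  cat(sprintf("\nEstimated rank: %d  =>  system classified as %s (%d%% level)\n",
              x$rank, x$classification, round(100 * x$level)))
  if (!is.na(x$beta0_hat)) {
    cat(sprintf("Cointegrating vector (1, beta0)': beta0 = %.4f\n", x$beta0_hat))
  }
  invisible(x)
}

#' @export
summary.johansen <- function(object, ...) {
  print(object)
  cat("\nEigenvalues:", format(object$eigenvalues, digits = 4), "\n")
  cat("Loadings alpha (leading column):",
      format(object$alpha[, 1], digits = 4), "\n")
  cat(sprintf("T_eff = %d, lagged differences = %d\n",
              object$fit$T_eff, object$fit$lag_diffs))
  invisible(object)
}

#' @export
coef.johansen <- function(object, ...) {
  list(beta = object$beta, alpha = object$alpha[, 1],
       Gamma = object$fit$Gamma)
}

#' @export
residuals.johansen <- function(object, ...) object$fit$residuals

#' @export
plot.johansen <- function(x, original = NULL, ...) {
  if (!is.na(x$beta0_hat) && !is.null(original)) {
    m <- as.matrix(original)
    ec <- m[, 1] + x$beta0_hat * m[, 2]
    graphics::plot(ec, type = "l", xlab = "t",
                   ylab = "equilibrium error  y1 + beta0 * y2", ...)
    graphics::abline(h = mean(ec), lty = 2)
  } else {
    graphics::matplot(x$fit$residuals, type = "l", lty = 1,
                      xlab = "t", ylab = "VECM residuals", ...)
  }
  invisible(x)
}
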