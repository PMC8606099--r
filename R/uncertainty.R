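# Interval estimation: multivariate delta method over the block-diagonal
# joint covariance, and the nonparametric percentile (pairs) bootstrap.

#' Delta-method variance of a smooth function of theta
#'
#' Computes `Var(f(theta)) = grad' Sigma_theta grad` with the gradient
#' obtained by central finite differences (per-coordinate step
#' `1e-6 * max(1, |theta_j|)`) and `Sigma_theta` the block-diagonal joint
#' covariance of the parameter estimate.
#'
#' @param measure Function taking a stacked parameter vector (the ordering
#'   of `coef(theta)`) and returning a finite scalar.
#' @param theta A `theta_estimate`.
#' @return A `delta_result`: list with `estimate`, `variance`, `gradient`
#'   and the 1.96-Wald `ci`.
#' @export
delta_variance <- function(measure, theta) {
  th <- coef(theta)
  Sigma <- vcov(theta)
  est <- measure(th)
  if (!is.finite(est))
    pm_computation_error("measure is nonfinite at the parameter estimate")
  q <- length(th)
  grad <- numeric(q)
  for (j in seq_len(q)) {
    h <- 1e-6 * max(1, abs(th[j]))
    up <- th; up[j] <- th[j] + h
    dn <- th; dn[j] <- th[j] - h
    fu <- measure(up); fd <- measure(dn)
    if (!is.finite(fu) || !is.finite(fd))
      pm_computation_error(sprintf(
        "measure is nonfinite at a perturbed point (coordinate %d)", j))
    grad[j] <- (fu - fd) / (2 * h)
  }
  v <- drop(crossprod(grad, Sigma %*% grad))
  if (v < -1e-12)
    pm_computation_error("delta-method variance is negative beyond numerical noise")
  v <- max(v, 0)
  structure(list(estimate = est, variance = v, gradient = grad,
                 ci = wald_ci(est, v)),
            class = "delta_result")
}

#' 95% Wald confidence interval
#'
#' `estimate +/- 1.96 * sqrt(variance)`, the normal-approximation interval
#' used with the delta-method variance.
#'
#' @param estimate Point estimate.
#' @param variance Nonnegative variance.
#' @return Numeric vector `c(lower, upper)`.
#' @export
wald_ci <- function(estimate, variance) {
  if (variance < 0) pm_validation_error("variance must be nonnegative")
  half <- 1.96 * sqrt(variance)
  c(lower = estimate - half, upper = estimate + half)
}

# Measure closure factory: maps a stacked theta vector to one mediation
# measure, holding the request fixed. Used by the delta method and by the
# analysis pipelines.
measure_function <- function(theta, case, what = c("nie", "mp", "nde", "te"),
                             x_star = 0, x_new = 1, w_out = NULL,
                             w_med = NULL, expression = "exact", nodes = 40L) {
  what <- match.arg(what)
  force(theta)
  function(values) {
    th <- theta_update(theta, values)
    est <- mediation_measures(th, case, x_star, x_new, w_out, w_med,
                              expression, nodes)
    est[[what]]
  }
}

#' Percentile bootstrap confidence intervals
#'
#' Resamples the dataset's rows (outcome, exposure, mediator and covariates
#' jointly) with replacement, re-runs the full estimator pipeline on each
#' resample, and forms per-measure 95% confidence intervals from the 2.5th
#' and 97.5th empirical percentiles (linear interpolation between order
#' statistics, `quantile type 7`). Resamples whose refit fails -- separation,
#' non-convergence, or a degenerate draw with constant exposure/mediator --
#' are recorded and excluded from the percentile computation; more than 20%
#' failures aborts with an error since the interval would be unreliable.
#'
#' Reproducibility: the user seed deterministically spawns one sub-seed per
#' resample, so the result is independent of execution order.
#'
#' @param data A [mediation_data].
#' @param estimator Function of a `mediation_data` returning a named numeric
#'   vector of measures (e.g. `c(nie = ..., mp = ...)`).
#' @param R Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return A `bootstrap_result`: `replicates` (R x k matrix, `NA` rows for
#'   failures), `ci` (2 x k), `n_failed`, `seed`.
#' @export
percentile_bootstrap <- function(data, estimator, R = 1000L, seed) {
  if (R < 100L) pm_validation_error("use at least 100 bootstrap resamples")
  if (missing(seed) || is.null(seed))
    pm_validation_error("an explicit seed is required for the bootstrap")
  n <- data$n
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, R)
  reps <- NULL
  n_failed <- 0L
  for (r in seq_len(R)) {
    set.seed(sub_seeds[r])
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data
    boot$y <- data$y[idx]; boot$x <- data$x[idx]; boot$m <- data$m[idx]
    boot$w <- data$w[idx, , drop = FALSE]
    est <- if (var(boot$x) == 0 || var(boot$m) == 0 ||
               (data$y_type == "binary" && var(boot$y) == 0)) {
      NULL  # degenerate resample
    } else {
      tryCatch(estimator(boot), prodmed_error = function(e) NULL,
               error = function(e) NULL)
    }
    if (is.null(reps) && !is.null(est))
      reps <- matrix(NA_real_, R, length(est),
                     dimnames = list(NULL, names(est)))
    if (is.null(est)) n_failed <- n_failed + 1L
    else reps[r, ] <- est
  }
  if (is.null(reps) || n_failed > 0.2 * R)
    pm_computation_error(sprintf(
      "%d of %d bootstrap resamples failed; percentile interval unreliable",
      n_failed, R))
  ci <- apply(reps, 2L, quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, type = 7, names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(list(replicates = reps, ci = ci, n_failed = n_failed,
                 R = R, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> R = %d (%d failed), seed = %d\n",
              x$R, x$n_failed, x$seed))
  print(x$ci)
  invisible(x)
}
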