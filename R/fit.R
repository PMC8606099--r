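# Estimating-equation fits for the outcome and mediator regressions.
#
# Both models are fitted by solving the unweighted canonical estimating
# equation U = sum_i d mu_i / d beta * V_i^{-1} (y_i - mu_i) = 0 with the
# canonical working variance (constant for the identity link, mu(1-mu) for
# the logit link), i.e. ordinary least squares and logistic maximum
# likelihood. Covariances are robust sandwich estimators by default; the
# model-based (inverse-information) covariance is kept alongside.

# Solve the estimating equation for one GLM with canonical link.
# X: n x q design (first column intercept). Returns a "model_fit".
ee_glm <- function(X, y, link = c("identity", "logit"),
                   max_iter = 100L, tol = 1e-10, sep_limit = 20) {
  link <- match.arg(link)
  n <- nrow(X); q <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < q) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):q]]
    pm_validation_error(sprintf(
      "rank-deficient design matrix; collinear column(s): %s",
      paste(dep, collapse = ", ")))
  }
  converged <- TRUE
  n_iter <- 0L
  if (link == "identity") {
    # exact one-step root of U(beta) = X'(y - X beta) = 0
    beta <- qr.coef(qrX, y)
    mu <- drop(X %*% beta)
    wts <- rep(1, n)
  } else {
    beta <- rep(0, q)
    repeat {
      eta <- drop(X %*% beta)
      mu <- expit(eta)
      score <- colMeans(X * (y - mu))
      if (max(abs(score)) < tol) break
      if (n_iter >= max_iter) { converged <- FALSE; break }
      wts <- mu * (1 - mu)
      # Newton scoring step; ridge-free, guarded against singular info
      info <- crossprod(X * wts, X)
      step <- tryCatch(solve(info, colSums(X * (y - mu))),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) { converged <- FALSE; break }
      beta <- beta + step
      n_iter <- n_iter + 1L
    }
    mu <- expit(drop(X %*% beta))
    wts <- mu * (1 - mu)
  }
  separated <- link == "logit" && any(abs(beta) > sep_limit)
  scores <- X * (y - mu)                      # n x q per-subject scores
  bread <- crossprod(X * wts, X) / n          # average score derivative (sign dropped)
  cov_sand <- if (converged && !separated)
    sandwich_covariance(scores, bread) else matrix(NA_real_, q, q)
  cov_model <- if (!converged || separated) {
    matrix(NA_real_, q, q)
  } else if (link == "identity") {
    s2 <- mean((y - mu)^2)
    s2 * chol2inv(qr.R(qrX))
  } else {
    solve(crossprod(X * wts, X))
  }
  dimnames(cov_sand) <- dimnames(cov_model) <- list(colnames(X), colnames(X))
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 covariance = cov_sand,
                 covariance_model_based = cov_model,
                 link = link, converged = converged, separated = separated,
                 n_iterations = n_iter, n = n,
                 fitted = mu, residuals = y - mu,
                 scores = scores, bread = bread),
            class = "model_fit")
}

#' Robust sandwich covariance from scores and bread
#'
#' Computes the estimating-equation covariance `A^{-1} B A^{-T} / n`, where
#' `A` is the average per-subject score derivative ("bread") and
#' `B` the average outer product of per-subject scores ("meat"). The single
#' `1/n` factor scales the result to the variance of the estimator.
#'
#' @param score_contributions `n x q` matrix of per-subject scores, rows
#'   summing to (numerically) zero at the solution.
#' @param bread `q x q` average score derivative; must be invertible.
#' @return `q x q` covariance matrix.
#' @export
sandwich_covariance <- function(score_contributions, bread) {
  S <- as.matrix(score_contributions)
  A <- as.matrix(bread)
  n <- nrow(S); q <- ncol(S)
  qrA <- qr(A)
  if (qrA$rank < q) {
    dep <- colnames(A)[qrA$pivot[(qrA$rank + 1L):q]]
    if (is.null(dep)) dep <- paste0("column ", qrA$pivot[(qrA$rank + 1L):q])
    pm_validation_error(sprintf(
      "singular bread matrix; collinear column(s): %s",
      paste(dep, collapse = ", ")))
  }
  B <- crossprod(S) / n
  Ainv <- solve(qrA)
  V <- Ainv %*% B %*% t(Ainv) / n
  (V + t(V)) / 2
}

outcome_design <- function(data, covariates = NULL) {
  W <- select_covariates(data, covariates)
  X <- cbind("(Intercept)" = 1, x = data$x, m = data$m, W)
  X
}

mediator_design <- function(data, covariates = NULL) {
  W <- select_covariates(data, covariates)
  cbind("(Intercept)" = 1, x = data$x, W)
}

select_covariates <- function(data, covariates) {
  if (is.null(covariates)) return(data$w)
  if (is.character(covariates)) {
    missing_cols <- setdiff(covariates, colnames(data$w))
    if (length(missing_cols))
      pm_validation_error(sprintf("unknown covariate(s): %s",
                                  paste(missing_cols, collapse = ", ")))
    data$w[, covariates, drop = FALSE]
  } else data$w[, covariates, drop = FALSE]
}

#' Fit the outcome regression by its estimating equation
#'
#' Solves `U(beta) = 0` for the outcome model
#' `g(E(Y|X,M,W)) = beta0 + beta1 X + beta2 M + beta3' W` with `g` the
#' identity (continuous outcome) or logit (binary outcome) link. The identity
#' fit is the exact one-step least-squares root; the logit fit uses Newton
#' scoring (max 100 iterations, convergence when the maximum absolute average
#' score falls below 1e-10). Any logit coefficient exceeding 20 in absolute
#' value flags probable separation; the fit is returned with
#' `converged`/`separated` set rather than failing silently.
#'
#' @param data A [mediation_data] object.
#' @param link `"identity"` or `"logit"`; must agree with the declared
#'   outcome type.
#' @param covariates Optional subset (names or indices) of `data$w` columns
#'   to include; default all.
#' @return A `model_fit` object with elements `coefficients`, `covariance`
#'   (sandwich), `covariance_model_based`, `link`, `converged`, `separated`,
#'   `n_iterations`, per-subject `scores` and the `bread` matrix.
#' @export
fit_outcome_model <- function(data, link = c("identity", "logit"),
                              covariates = NULL) {
  link <- match.arg(link)
  expected <- if (data$y_type == "binary") "logit" else "identity"
  if (link != expected)
    pm_validation_error(sprintf(
      "link '%s' inconsistent with declared %s outcome", link, data$y_type))
  fit <- ee_glm(outcome_design(data, covariates), data$y, link)
  fit$role <- "outcome"
  fit
}

#' Fit the mediator regression by its estimating equations
#'
#' Solves `U(gamma) = 0` for the mediator model
#' `h(E(M|X,W)) = gamma0 + gamma1 X + gamma2' W`. For the identity link the
#' residual variance is additionally estimated as the exact root of
#' `U(sigma^2) = sum_i {sigma^2 - r_i^2} = 0`, i.e.
#' `sigma2 = mean(r_i^2)` (divisor `n`, not `n - p`), with estimating-equation
#' variance `var(sigma2) = mean((sigma2 - r_i^2)^2) / n`.
#'
#' @inheritParams fit_outcome_model
#' @return A `model_fit`; for the identity link with extra fields `sigma2`,
#'   `var_sigma2`, and per-subject `sigma2_scores`.
#' @export
fit_mediator_model <- function(data, link = c("identity", "logit"),
                               covariates = NULL) {
  link <- match.arg(link)
  expected <- if (data$m_type == "binary") "logit" else "identity"
  if (link != expected)
    pm_validation_error(sprintf(
      "link '%s' inconsistent with declared %s mediator", link, data$m_type))
  fit <- ee_glm(mediator_design(data, covariates), data$m, link)
  fit$role <- "mediator"
  if (link == "identity") {
    r <- fit$residuals
    sigma2 <- mean(r^2)
    if (sigma2 < 1e-12)
      pm_computation_error(
        "degenerate mediator: residual variance is zero (mediator is an exact linear function of the design)")
    fit$sigma2 <- sigma2
    fit$sigma2_scores <- sigma2 - r^2
    fit$var_sigma2 <- sum((sigma2 - r^2)^2) / fit$n^2
  }
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s model, %s link, n = %d%s\n", x$role %||% "",
              x$link, x$n,
              if (!x$converged) " [NOT CONVERGED]"
              else if (isTRUE(x$separated)) " [SEPARATION SUSPECTED]" else ""))
  print(x$coefficients)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the joint parameter estimate with block-diagonal covariance
#'
#' Stacks the outcome coefficients, mediator coefficients and (optionally)
#' the mediator residual variance into the joint vector
#' `theta = (beta, gamma, sigma2)`. Because the three estimating equations
#' are asymptotically uncorrelated, the joint covariance is strictly
#' block-diagonal: all cross-blocks are exactly zero.
#'
#' @param outcome_fit,mediator_fit Converged `model_fit` objects from
#'   [fit_outcome_model] and [fit_mediator_model].
#' @param include_sigma2 Include the mediator residual variance in `theta`?
#'   Default: yes when the outcome is logistic and the mediator identity
#'   (the only configuration whose exact expressions consume it).
#' @param covariance Which per-block covariance to use.
#' @return A `theta_estimate` with fields `beta`, `gamma`, `sigma2` (or
#'   `NULL`), `cov_beta`, `cov_gamma`, `var_sigma2`; [coef()] returns the
#'   stacked vector, [vcov()] the block-diagonal matrix.
#' @export
assemble_theta <- function(outcome_fit, mediator_fit,
                           include_sigma2 = NULL,
                           covariance = c("sandwich", "model_based")) {
  covariance <- match.arg(covariance)
  for (f in list(outcome_fit, mediator_fit)) {
    if (!f$converged)
      pm_computation_error(sprintf("%s model did not converge", f$role %||% "a"))
    if (isTRUE(f$separated))
      pm_computation_error(sprintf(
        "%s model shows probable separation (|coefficient| > 20)", f$role %||% "a"))
  }
  if (is.null(include_sigma2))
    include_sigma2 <- outcome_fit$link == "logit" &&
      mediator_fit$link == "identity" && !is.null(mediator_fit$sigma2)
  if (include_sigma2 && is.null(mediator_fit$sigma2))
    pm_validation_error("sigma2 requested but the mediator model has no residual variance (logit link)")
  pick <- function(f) if (covariance == "sandwich") f$covariance
                      else f$covariance_model_based
  structure(list(beta = outcome_fit$coefficients,
                 gamma = mediator_fit$coefficients,
                 sigma2 = if (include_sigma2) mediator_fit$sigma2 else NULL,
                 cov_beta = pick(outcome_fit),
                 cov_gamma = pick(mediator_fit),
                 var_sigma2 = if (include_sigma2) mediator_fit$var_sigma2 else NULL),
            class = "theta_estimate")
}

# Construct a theta_estimate from known parameter values (no uncertainty);
# used by the simulation solvers and for evaluating truths.
theta_values <- function(beta, gamma, sigma2 = NULL) {
  qb <- length(beta); qg <- length(gamma)
  structure(list(beta = beta, gamma = gamma, sigma2 = sigma2,
                 cov_beta = matrix(0, qb, qb),
                 cov_gamma = matrix(0, qg, qg),
                 var_sigma2 = if (!is.null(sigma2)) 0 else NULL),
            class = "theta_estimate")
}

#' @export
coef.theta_estimate <- function(object, ...) {
  c(setNames(object$beta, paste0("beta.", names(object$beta) %||%
                                   seq_along(object$beta))),
    setNames(object$gamma, paste0("gamma.", names(object$gamma) %||%
                                    seq_along(object$gamma))),
    if (!is.null(object$sigma2)) c(sigma2 = object$sigma2))
}

#' @export
vcov.theta_estimate <- function(object, ...) {
  qb <- length(object$beta); qg <- length(object$gamma)
  qs <- if (is.null(object$sigma2)) 0L else 1L
  q <- qb + qg + qs
  V <- matrix(0, q, q)
  V[seq_len(qb), seq_len(qb)] <- object$cov_beta
  V[qb + seq_len(qg), qb + seq_len(qg)] <- object$cov_gamma
  if (qs) V[q, q] <- object$var_sigma2
  dimnames(V) <- list(names(coef(object)), names(coef(object)))
  V
}

# Rebuild a theta_estimate with the stacked parameter vector replaced;
# covariance blocks are carried over unchanged (used by numeric gradients).
theta_update <- function(theta, values) {
  qb <- length(theta$beta); qg <- length(theta$gamma)
  theta$beta[] <- values[seq_len(qb)]
  theta$gamma[] <- values[qb + seq_len(qg)]
  if (!is.null(theta$sigma2)) theta$sigma2 <- values[qb + qg + 1L]
  theta
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat("<theta_estimate>\n  beta: ", paste(signif(x$beta, 4), collapse = ", "),
      "\n  gamma:", paste(signif(x$gamma, 4), collapse = ", "), "\n")
  if (!is.null(x$sigma2)) cat("  sigma2:", signif(x$sigma2, 4), "\n")
  invisible(x)
}
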