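# Mediation measures (NIE, NDE, TE, MP) for the four outcome/mediator data
# types, each as a function of the joint parameter estimate theta.
#
# Scale: difference of conditional means for a continuous outcome
# (cases 1-2); log odds ratio for a binary outcome (cases 3-4). For binary
# outcomes three expression variants exist: "exact" (no rare-outcome
# assumption), "approx" (rare-outcome approximation) and, for a continuous
# mediator only, "probit" (scaled normal-CDF approximation with s = 1/1.6).

#' Exponentiated linear predictor excluding the mediator term
#'
#' Evaluates `exp(c0 + c1 * x + c2' w)`, the `kappa(x, w)` /
#' `eta(x, w)` building blocks of the binary-mediator and binary-outcome
#' expressions. The linear predictor is clipped at +/- 700 (with a warning)
#' to protect `exp()` from overflow.
#'
#' @param coeffs Numeric vector `(intercept, slope_x, slopes_w...)`.
#' @param x Exposure value.
#' @param w Covariate values (length `length(coeffs) - 2`, possibly empty).
#' @return Positive scalar.
#' @export
exp_linear <- function(coeffs, x, w = numeric(0)) {
  if (length(coeffs) != 2L + length(w))
    pm_validation_error("coeffs must have length 2 + length(w)")
  lp <- coeffs[1L] + coeffs[2L] * x + sum(coeffs[-(1:2)] * w)
  if (abs(lp) > 700) {
    warning("linear predictor clipped at +/-700 before exponentiation")
    lp <- sign(lp) * 700
  }
  exp(lp)
}

#' Logistic-normal moment ratio by Gauss-Hermite quadrature
#'
#' Computes the ratio `int exp(beta2 m) tau(m) dm / int tau(m) dm`, where
#' `tau(m)` is proportional to `phi(m; mu, sigma2) / (1 + exp(beta_lin +
#' beta2 m))`, i.e. the normal density of the mediator times the complement
#' of the outcome's logistic probability. These one-dimensional
#' logistic-normal integrals have no closed form; they are evaluated by
#' Gauss-Hermite quadrature after the substitution
#' `m = mu + sqrt(2 sigma2) z`, in log space for overflow safety.
#'
#' @param beta_lin Logistic offset `beta0 + beta1 x + beta3' w` (mediator
#'   term excluded).
#' @param beta2 Mediator coefficient in the outcome model.
#' @param mu Mediator mean `gamma0 + gamma1 x' + gamma2' w`.
#' @param sigma2 Mediator residual variance (> 0).
#' @param nodes Number of quadrature nodes (>= 10; default 40).
#' @return Positive scalar ratio; equals 1 exactly when `beta2 = 0`.
#' @export
ghq_logistic_normal_ratio <- function(beta_lin, beta2, mu, sigma2,
                                      nodes = 40L) {
  if (sigma2 <= 0) pm_validation_error("sigma2 must be positive")
  if (nodes < 10L) pm_validation_error("use at least 10 quadrature nodes")
  gh <- gauss_hermite(nodes)
  m <- mu + sqrt(2 * sigma2) * gh$nodes
  logw <- log(gh$weights)
  log_den_terms <- logw - log1pexp(beta_lin + beta2 * m)
  log_num_terms <- log_den_terms + beta2 * m
  out <- exp(logsumexp(log_num_terms) - logsumexp(log_den_terms))
  if (!is.finite(out))
    pm_computation_error(
      "nonfinite logistic-normal quadrature; increase nodes or rescale the problem")
  out
}

#' Mediation proportion from effect components
#'
#' `MP = NIE / (NIE + NDE)`. The ratio is never clamped: sign-discordant
#' effects legitimately give values outside `[0, 1]`.
#'
#' @param nie,nde Natural indirect and direct effects on a common scale.
#' @return `nie / (nie + nde)`.
#' @export
mp_from <- function(nie, nde) {
  te <- nie + nde
  if (abs(te) <= 1e-12)
    pm_computation_error("mediation proportion undefined: total effect is (numerically) zero")
  nie / te
}

linpred <- function(intercept, slope, x, slopes_w, w) {
  intercept + slope * x + (if (length(w)) sum(slopes_w * w) else 0)
}

# split beta into (b0, b1, b2, b3) and gamma into (g0, g1, g2)
split_beta <- function(beta) list(b0 = beta[1L], b1 = beta[2L], b2 = beta[3L],
                                  b3 = beta[-(1:3)])
split_gamma <- function(gamma) list(g0 = gamma[1L], g1 = gamma[2L],
                                    g2 = gamma[-(1:2)])

#' Evaluate mediation measures from a parameter estimate
#'
#' Computes NIE, NDE, TE and MP for an exposure change from `x_star` to
#' `x_new`, conditional on covariate values `w_out` (outcome model) and
#' `w_med` (mediator model), for the requested data-type case:
#'
#' * case 1 (continuous outcome, continuous mediator): `NIE = beta2 gamma1
#'   dx`, `NDE = beta1 dx` (difference scale; covariate-free).
#' * case 2 (continuous outcome, binary mediator): `NIE = beta2 (expit(g(x))
#'   - expit(g(x*)))` with `g` the mediator linear predictor.
#' * case 3 (binary outcome, continuous mediator): `"exact"` via
#'   logistic-normal quadrature ratios; `"approx"` the rare-outcome product
#'   formulas; `"probit"` the scaled normal-CDF closed form (`s = 1/1.6`).
#'   Log-odds-ratio scale.
#' * case 4 (binary outcome, binary mediator): `"exact"` by enumeration over
#'   the binary mediator (cross-checked against the closed forms); `"approx"`
#'   the rare-outcome expressions. Log-odds-ratio scale.
#'
#' @param theta A `theta_estimate` (from [assemble_theta]); case 3 exact
#'   requires its `sigma2` component.
#' @param case Integer 1-4 identifying the outcome/mediator data types.
#' @param x_star,x_new Baseline and comparison exposure levels.
#' @param w_out,w_med Conditioning covariate values for the outcome and
#'   mediator models (default all zero).
#' @param expression `"exact"`, `"approx"` or `"probit"`; cases 1-2 have a
#'   single expression and ignore this argument.
#' @param nodes Gauss-Hermite node count for case 3 exact.
#' @return A `mediation_estimate`: list with `nie`, `nde`, `te`, `mp`
#'   (`NA` with `mp_defined = FALSE` when TE is numerically zero), `scale`,
#'   `case`, `expression`.
#' @export
mediation_measures <- function(theta, case, x_star = 0, x_new = 1,
                               w_out = NULL, w_med = NULL,
                               expression = c("exact", "approx", "probit"),
                               nodes = 40L) {
  expression <- match.arg(expression)
  case <- as.integer(case)
  if (!case %in% 1:4) pm_validation_error("case must be 1, 2, 3 or 4")
  if (expression == "probit" && case != 3L)
    pm_validation_error("the probit approximation is defined only for case 3")
  if (case %in% 1:2 ) expression <- "exact"
  nb_w <- length(theta$beta) - 3L
  ng_w <- length(theta$gamma) - 2L
  if (is.null(w_out)) w_out <- rep(0, nb_w)
  if (is.null(w_med)) w_med <- rep(0, ng_w)
  if (length(w_out) != nb_w || length(w_med) != ng_w)
    pm_validation_error("conditioning values do not match the fitted covariate dimensions")
  b <- split_beta(theta$beta); g <- split_gamma(theta$gamma)
  dx <- x_new - x_star
  scale <- if (case >= 3L) "log_odds_ratio" else "difference"

  if (case == 1L) {
    nie <- b$b2 * g$g1 * dx
    nde <- b$b1 * dx
  } else if (case == 2L) {
    p1 <- expit(linpred(g$g0, g$g1, x_new, g$g2, w_med))
    p0 <- expit(linpred(g$g0, g$g1, x_star, g$g2, w_med))
    nie <- b$b2 * (p1 - p0)
    nde <- b$b1 * dx
  } else if (case == 3L) {
    if (expression == "approx") {
      nie <- b$b2 * g$g1 * dx
      nde <- b$b1 * dx
    } else if (expression == "probit") {
      s <- 1 / 1.6
      sig2 <- theta$sigma2
      if (is.null(sig2)) pm_validation_error("probit expression requires sigma2 in theta")
      denom <- sqrt(1 + s^2 * b$b2^2 * sig2)
      a <- function(xo, xm)
        (s * linpred(b$b0, b$b1, xo, b$b3, w_out) +
           s * b$b2 * linpred(g$g0, g$g1, xm, g$g2, w_med)) / denom
      lf <- function(z) logit(pnorm(z))
      nie <- lf(a(x_new, x_new)) - lf(a(x_new, x_star))
      nde <- lf(a(x_new, x_star)) - lf(a(x_star, x_star))
    } else {
      sig2 <- theta$sigma2
      if (is.null(sig2))
        pm_validation_error("case 3 exact expressions require sigma2 in theta")
      lr <- function(x_med, x_out) {
        log(ghq_logistic_normal_ratio(
          beta_lin = linpred(b$b0, b$b1, x_out, b$b3, w_out),
          beta2 = b$b2,
          mu = linpred(g$g0, g$g1, x_med, g$g2, w_med),
          sigma2 = sig2, nodes = nodes))
      }
      nie <- lr(x_new, x_new) - lr(x_star, x_new)
      nde <- b$b1 * dx + lr(x_star, x_new) - lr(x_star, x_star)
    }
  } else {
    kap <- function(x) exp_linear(theta$gamma, x, w_med)
    if (expression == "approx") {
      k1 <- kap(x_new); k0 <- kap(x_star)
      nie <- log((1 + k0) * (1 + exp(b$b2) * k1)) -
             log((1 + k1) * (1 + exp(b$b2) * k0))
      nde <- b$b1 * dx
    } else {
      pot <- function(xo, xm)
        enumerate_case4_logit_potential(theta, xo, xm, w_out, w_med)
      nie <- pot(x_new, x_new) - pot(x_new, x_star)
      nde <- pot(x_new, x_star) - pot(x_star, x_star)
      cf_nie <- case4_closed_nie(theta, x_star, x_new, w_out, w_med)
      cf_nde <- case4_closed_nde(theta, x_star, x_new, w_out, w_med)
      if (max(abs(cf_nie - nie), abs(cf_nde - nde)) > 1e-8)
        warning(sprintf(
          "case 4 closed form disagrees with enumeration by %.3g; enumeration reported",
          max(abs(cf_nie - nie), abs(cf_nde - nde))))
    }
  }
  nie <- unname(nie); nde <- unname(nde)
  te <- nie + nde
  mp <- tryCatch(mp_from(nie, nde), prodmed_computation_error = function(e) NA_real_)
  structure(list(nie = nie, nde = nde, te = te, mp = mp,
                 mp_defined = !is.na(mp), scale = scale,
                 case = case, expression = expression,
                 x_star = x_star, x_new = x_new),
            class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<mediation_estimate> case %d, %s expression (%s scale)\n",
              x$case, x$expression, x$scale))
  cat(sprintf("  NIE = %.*g, NDE = %.*g, TE = %.*g, MP = %s\n",
              digits, x$nie, digits, x$nde, digits, x$te,
              if (x$mp_defined) sprintf("%.*g", digits, x$mp)
              else "undefined (TE = 0)"))
  invisible(x)
}

#' Exact g-scale potential-outcome mean for a binary mediator
#'
#' For logit-linked outcome and mediator models, returns
#' `logit(E[Y_{x_outcome, M_{x_mediator}} | w])`, obtained exactly by
#' enumerating the binary mediator:
#' `P(Y=1|x,M=1,w) P(M=1|x',w) + P(Y=1|x,M=0,w) P(M=0|x',w)`.
#' This is the canonical case-4 computation and serves as the oracle for the
#' closed-form expressions.
#'
#' @param theta A `theta_estimate` with logit-link coefficient vectors.
#' @param x_outcome Exposure level set in the outcome model.
#' @param x_mediator Exposure level generating the mediator distribution.
#' @param w_out,w_med Conditioning covariate values.
#' @return The logit of the potential-outcome mean.
#' @export
enumerate_case4_logit_potential <- function(theta, x_outcome, x_mediator,
                                            w_out = NULL, w_med = NULL) {
  b <- split_beta(theta$beta); g <- split_gamma(theta$gamma)
  if (is.null(w_out)) w_out <- rep(0, length(b$b3))
  if (is.null(w_med)) w_med <- rep(0, length(g$g2))
  p_m <- expit(linpred(g$g0, g$g1, x_mediator, g$g2, w_med))
  lp_out <- linpred(b$b0, b$b1, x_outcome, b$b3, w_out)
  p <- expit(lp_out + b$b2) * p_m + expit(lp_out) * (1 - p_m)
  if (p <= 0 || p >= 1)
    pm_computation_error("potential-outcome probability of exactly 0 or 1: logit undefined")
  logit(p)
}

# Closed-form case 4 exact NIE. The published second log term does not
# vanish at beta2 = 0; matching the enumeration oracle requires flipping its
# sign (equivalently interchanging the kappa(x,w) and kappa(x*,w) arguments
# in that term). With A(c) = 1 + e^{b2} eta(x) + kappa(c)(1 + eta(x)) and
# B(c) = 1 + e^{b2} eta(x) + e^{b2} kappa(c)(1 + eta(x)):
#   NIE = log{A(x*)/A(x)} + log{B(x)/B(x*)}.
case4_closed_nie <- function(theta, x_star, x_new, w_out = NULL, w_med = NULL) {
  b <- split_beta(theta$beta)
  if (is.null(w_out)) w_out <- rep(0, length(b$b3))
  if (is.null(w_med)) w_med <- rep(0, length(theta$gamma) - 2L)
  eta_x <- exp_linear(theta$beta[-3L], x_new, w_out)
  kap <- function(x) exp_linear(theta$gamma, x, w_med)
  eb2 <- exp(b$b2)
  A <- function(c) 1 + eb2 * eta_x + kap(c) * (1 + eta_x)
  B <- function(c) 1 + eb2 * eta_x + eb2 * kap(c) * (1 + eta_x)
  log(A(x_star) / A(x_new)) + log(B(x_new) / B(x_star))
}

# Closed-form case 4 exact NDE (verified correct as published).
case4_closed_nde <- function(theta, x_star, x_new, w_out = NULL, w_med = NULL) {
  b <- split_beta(theta$beta)
  if (is.null(w_out)) w_out <- rep(0, length(b$b3))
  if (is.null(w_med)) w_med <- rep(0, length(theta$gamma) - 2L)
  eta <- function(x) exp_linear(theta$beta[-3L], x, w_out)
  kap_s <- exp_linear(theta$gamma, x_star, w_med)
  eb2 <- exp(b$b2)
  A <- function(xo) 1 + eb2 * eta(xo) + kap_s * (1 + eta(xo))
  B <- function(xo) 1 + eb2 * eta(xo) + eb2 * kap_s * (1 + eta(xo))
  b$b1 * (x_new - x_star) + log(A(x_star) / A(x_new)) + log(B(x_new) / B(x_star))
}
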