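# Simulation engine: generators calibrated to hit target total effect,
# mediation proportion, exposure-mediator correlation and baseline
# prevalences; replication studies; operating-characteristic summaries
# (median percent bias, coverage rates, variance ratio).

#' Solve the exposure-mediator slope for a target correlation
#'
#' Calibrates `gamma1` so the generated exposure-mediator correlation equals
#' `target_corr`, with `X ~ Bernoulli(exposure_prob)`.
#'
#' Continuous mediator (`M | X ~ N(gamma0 + gamma1 X, 1)`): closed form,
#' `gamma1 = rho / sqrt(p(1-p)(1 - rho^2))`. Binary mediator
#' (`logit P(M=1|X) = gamma0 + gamma1 X` with baseline prevalence
#' `P(M=1|X=0) = baseline_prev`): numeric root in the exposed-arm prevalence
#' `p1`, then `gamma1 = logit(p1) - logit(p0)`.
#'
#' @param mediator_type `"continuous"` or `"binary"`.
#' @param target_corr Target `Corr(X, M)`.
#' @param baseline_prev Baseline mediator prevalence (binary mediator only).
#' @param exposure_prob `P(X = 1)`.
#' @return The calibrated slope `gamma1`.
#' @export
solve_gamma1_for_correlation <- function(mediator_type = c("continuous", "binary"),
                                         target_corr,
                                         baseline_prev = NULL,
                                         exposure_prob = 0.5) {
  mediator_type <- match.arg(mediator_type)
  p <- exposure_prob
  if (p <= 0 || p >= 1) pm_validation_error("exposure_prob must be in (0, 1)")
  if (abs(target_corr) >= 1)
    pm_validation_error("target correlation must be in (-1, 1)")
  if (target_corr == 0) return(0)
  if (mediator_type == "continuous") {
    return(target_corr / sqrt(p * (1 - p) * (1 - target_corr^2)))
  }
  p0 <- baseline_prev
  if (is.null(p0) || p0 <= 0 || p0 >= 1)
    pm_validation_error("binary mediator requires baseline_prev in (0, 1)")
  corr_at <- function(p1) {
    pbar <- (1 - p) * p0 + p * p1
    sqrt(p * (1 - p)) * (p1 - p0) / sqrt(pbar * (1 - pbar))
  }
  eps <- 1e-10
  if (target_corr > 0) {
    lim <- corr_at(1 - eps)
    if (target_corr >= lim)
      pm_validation_error(sprintf(
        "correlation %.3f unattainable; feasible range is (%.3f, %.3f)",
        target_corr, corr_at(eps), lim))
    p1 <- uniroot(function(z) corr_at(z) - target_corr,
                  c(p0 + eps, 1 - eps), tol = 1e-12)$root
  } else {
    lim <- corr_at(eps)
    if (target_corr <= lim)
      pm_validation_error(sprintf(
        "correlation %.3f unattainable; feasible range is (%.3f, %.3f)",
        target_corr, lim, corr_at(1 - eps)))
    p1 <- uniroot(function(z) corr_at(z) - target_corr,
                  c(eps, p0 - eps), tol = 1e-12)$root
  }
  logit(p1) - logit(p0)
}

#' Logit intercept from a baseline prevalence
#'
#' Returns `logit(prev)`, the intercept making the model's baseline
#' probability (all other terms zero) equal `prev`.
#'
#' @param prev Probability strictly between 0 and 1.
#' @export
intercept_from_prevalence <- function(prev) {
  if (prev <= 0 || prev >= 1)
    pm_validation_error("prevalence must be strictly between 0 and 1")
  logit(prev)
}

#' Closed-form outcome coefficients for the continuous-outcome cases
#'
#' Inverts the case-1/2 mediation expressions at the targets:
#' `beta1 = (1 - MP) TE` and `beta2 = MP TE / gamma1` (case 1) or
#' `beta2 = MP TE / (expit(gamma0 + gamma1) - expit(gamma0))` (case 2).
#'
#' @param case 1 or 2.
#' @param te,mp Target total effect (difference scale) and mediation
#'   proportion.
#' @param gamma0 Mediator-model intercept (case 2).
#' @param gamma1 Mediator-model slope.
#' @return Named vector `c(beta1, beta2)`.
#' @export
solve_linear_outcome_params <- function(case, te, mp, gamma0 = NULL, gamma1) {
  case <- as.integer(case)
  if (!case %in% 1:2) pm_validation_error("case must be 1 or 2")
  if (mp != 0 && gamma1 == 0)
    pm_validation_error("no mediated path possible: gamma1 = 0 with nonzero MP")
  beta1 <- (1 - mp) * te
  beta2 <- if (mp == 0) 0 else if (case == 1L) {
    mp * te / gamma1
  } else {
    if (is.null(gamma0)) pm_validation_error("case 2 requires gamma0")
    mp * te / (expit(gamma0 + gamma1) - expit(gamma0))
  }
  c(beta1 = beta1, beta2 = unname(beta2))
}

#' Outcome coefficients hitting exact targets for the binary-outcome cases
#'
#' Solves the two-equation system `NIE(beta1, beta2) = MP x TE` and
#' `NDE(beta1, beta2) = (1 - MP) x TE` (exact log-odds-ratio expressions)
#' for `(beta1, beta2)` by damped Newton iteration with a numeric Jacobian,
#' started at the rare-outcome approximate solution. Residuals at the root
#' are required below 1e-10.
#'
#' @param case 3 or 4.
#' @param te,mp Targets on the log odds ratio scale and in (0, 1).
#' @param beta0 Outcome intercept (fixes the baseline prevalence).
#' @param gamma Mediator coefficients `c(gamma0, gamma1)`.
#' @param sigma2 Mediator residual variance (case 3).
#' @param nodes Gauss-Hermite node count for case 3.
#' @return Named vector `c(beta1, beta2)`.
#' @export
solve_logistic_outcome_params <- function(case, te, mp, beta0, gamma,
                                          sigma2 = NULL, nodes = 40L) {
  case <- as.integer(case)
  if (!case %in% 3:4) pm_validation_error("case must be 3 or 4")
  if (case == 3L && is.null(sigma2)) sigma2 <- 1
  target <- c(mp * te, (1 - mp) * te)
  exact_at <- function(b) {
    th <- theta_values(beta = c(beta0, b[1L], b[2L]), gamma = gamma,
                       sigma2 = if (case == 3L) sigma2 else NULL)
    est <- mediation_measures(th, case, 0, 1, expression = "exact",
                              nodes = nodes)
    c(est$nie, est$nde)
  }
  if (mp == 0) {
    beta1 <- uniroot(function(b1) exact_at(c(b1, 0))[2L] - te,
                     interval = te + c(-5, 5), extendInt = "yes",
                     tol = 1e-12)$root
    return(c(beta1 = beta1, beta2 = 0))
  }
  # rare-outcome starting values
  b <- c((1 - mp) * te,
         if (case == 3L) mp * te / gamma[2L]
         else mp * te / (expit(gamma[1L] + gamma[2L]) - expit(gamma[1L])))
  f <- exact_at(b) - target
  for (iter in seq_len(100L)) {
    if (max(abs(f)) < 1e-12) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-7 * max(1, abs(b[j]))
      up <- b; up[j] <- b[j] + h
      dn <- b; dn[j] <- b[j] - h
      J[, j] <- (exact_at(up) - exact_at(dn)) / (2 * h)
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step))
      pm_computation_error("singular Jacobian in the coefficient solver")
    lambda <- 1
    repeat {
      bn <- b - lambda * step
      fn <- exact_at(bn) - target
      if (sum(fn^2) < sum(f^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    b <- bn; f <- fn
  }
  if (max(abs(f)) > 1e-10)
    pm_computation_error(sprintf(
      "coefficient solver did not converge (case %d, TE = %.4g, MP = %.3g, residual %.3g)",
      case, te, mp, max(abs(f))))
  c(beta1 = b[1L], beta2 = b[2L])
}

#' Define a simulation scenario
#'
#' Bundles the generator settings of one replication study: the data-type
#' case, sample size, target total effect and mediation proportion, baseline
#' prevalences, exposure-mediator correlation target, replication count and
#' seed, plus the sensitivity options (heteroskedastic or standardized-gamma
#' mediator errors; an optional binary confounder).
#'
#' Defaults mirror the reference design: `exposure_prob = 0.5`,
#' mediator baseline prevalence 0.2 (binary mediator), outcome baseline
#' prevalence 0.03 (binary outcome), `Corr(X, M) = 0.2`, mediator error
#' variance 1.
#'
#' @param case Data-type case 1-4.
#' @param n Sample size per replication.
#' @param te Target total effect (difference scale for cases 1-2, log odds
#'   ratio for 3-4).
#' @param mp Target mediation proportion in (0, 1).
#' @param reps Number of replications.
#' @param seed Integer seed; per-replication sub-seeds are derived from it.
#' @param exposure_prob,mediator_prev,outcome_prev,target_corr Generator
#'   calibration targets (see above).
#' @param variants Estimator expressions to evaluate: subset of
#'   `"exact"`, `"approx"`, `"probit"` (cases 1-2 always use their single
#'   expression).
#' @param bootstrap_R Optional bootstrap replication count per dataset
#'   (`NULL` = delta method only).
#' @param error_model Mediator error model for continuous mediators:
#'   `"normal"`, `"heteroskedastic"` (`Var(M|X) = eta0 + eta1 X` with
#'   `eta0` set so the average error variance is 1) or `"gamma"`
#'   (standardized gamma errors with skewness `skew`: shape `(2/s)^2`,
#'   scale `s/2`, centered and scaled to mean 0, variance 1).
#' @param eta1 Heteroskedasticity slope (0 to 1).
#' @param skew Gamma-error skewness coefficient.
#' @param confounder Optional binary confounder specification:
#'   `list(prevalence, coef_exposure, coef_mediator, coef_outcome)`.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(case, n, te, mp, reps, seed,
                                exposure_prob = 0.5, mediator_prev = 0.2,
                                outcome_prev = 0.03, target_corr = 0.2,
                                variants = NULL, bootstrap_R = NULL,
                                error_model = c("normal", "heteroskedastic", "gamma"),
                                eta1 = 0, skew = 1, confounder = NULL) {
  case <- as.integer(case)
  error_model <- match.arg(error_model)
  if (!case %in% 1:4) pm_validation_error("case must be 1, 2, 3 or 4")
  if (mp <= 0 || mp >= 1) pm_validation_error("mp must be in (0, 1)")
  if (n < 10) pm_validation_error("n too small")
  if (is.null(variants))
    variants <- if (case >= 3L) c("exact", "approx") else "exact"
  if (!all(variants %in% c("exact", "approx", "probit")))
    pm_validation_error("variants must be a subset of exact/approx/probit")
  if ("probit" %in% variants && case != 3L)
    pm_validation_error("probit variant only exists for case 3")
  if (case %in% c(1L, 2L)) variants <- "exact"
  if (error_model == "heteroskedastic" && (eta1 < 0 || eta1 > 1))
    pm_validation_error("eta1 must be in [0, 1]")
  if (!is.null(confounder)) {
    need <- c("prevalence", "coef_exposure", "coef_mediator", "coef_outcome")
    if (!all(need %in% names(confounder)))
      pm_validation_error(paste("confounder must supply:",
                                paste(need, collapse = ", ")))
  }
  structure(list(case = case, n = as.integer(n), te = te, mp = mp,
                 reps = as.integer(reps), seed = as.integer(seed),
                 exposure_prob = exposure_prob, mediator_prev = mediator_prev,
                 outcome_prev = outcome_prev, target_corr = target_corr,
                 variants = variants, bootstrap_R = bootstrap_R,
                 error_model = error_model, eta1 = eta1, skew = skew,
                 confounder = confounder),
            class = "simulation_scenario")
}

#' Solve the generator coefficients implied by a scenario
#'
#' Calibrates the mediator slope to the correlation target, the intercepts
#' to the baseline prevalences, and the outcome coefficients to the
#' (TE, MP) targets -- closed form for continuous outcomes, exact-expression
#' root-finding for binary outcomes. The implied exact measures reproduce
#' the targets to numerical precision (round-trip invariant).
#'
#' @param scenario A [simulation_scenario].
#' @return List with `beta = c(beta0, beta1, beta2)`,
#'   `gamma = c(gamma0, gamma1)`, `sigma2` (continuous mediator),
#'   `true_nie`, `true_mp`, and `approx_nie` (the rare-outcome approximate
#'   expression evaluated at the solved parameters; binary outcome only).
#' @export
solve_scenario_params <- function(scenario) {
  s <- scenario
  med_type <- if (s$case %in% c(2L, 4L)) "binary" else "continuous"
  gamma0 <- if (med_type == "binary") intercept_from_prevalence(s$mediator_prev) else 0
  gamma1 <- solve_gamma1_for_correlation(med_type, s$target_corr,
                                         baseline_prev = s$mediator_prev,
                                         exposure_prob = s$exposure_prob)
  sigma2 <- if (med_type == "continuous") 1 else NULL
  if (s$case %in% 1:2) {
    beta0 <- 0
    b12 <- solve_linear_outcome_params(s$case, s$te, s$mp, gamma0, gamma1)
  } else {
    beta0 <- intercept_from_prevalence(s$outcome_prev)
    b12 <- solve_logistic_outcome_params(s$case, s$te, s$mp, beta0,
                                         c(gamma0, gamma1), sigma2)
  }
  beta <- c(beta0 = beta0, b12)
  approx_nie <- if (s$case >= 3L) {
    th <- theta_values(unname(beta), c(gamma0, gamma1), sigma2)
    mediation_measures(th, s$case, expression = "approx")$nie
  } else NULL
  list(beta = unname(beta), gamma = c(gamma0, gamma1), sigma2 = sigma2,
       true_nie = s$mp * s$te, true_mp = s$mp, approx_nie = approx_nie)
}

#' Generate one dataset under a scenario
#'
#' Draws `n` subjects from the scenario's data-generating process:
#' `X ~ Bernoulli(exposure_prob)`; mediator normal (optionally
#' heteroskedastic or with standardized gamma errors) or Bernoulli via its
#' logistic model; outcome normal with unit variance or Bernoulli via its
#' logistic model. An optional binary confounder enters the exposure,
#' mediator and outcome linear predictors and is carried as a covariate
#' column.
#'
#' Uses the current RNG state; seed outside (the replication driver derives
#' a sub-seed per replication).
#'
#' @param scenario A [simulation_scenario].
#' @param params Solved coefficients from [solve_scenario_params].
#' @return A [mediation_data].
#' @export
generate_dataset <- function(scenario, params) {
  s <- scenario
  n <- s$n
  beta <- params$beta; gamma <- params$gamma
  has_c <- !is.null(s$confounder)
  if (has_c) {
    cf <- s$confounder
    C <- rbinom(n, 1L, cf$prevalence)
    # keep the marginal exposure prevalence near its target
    x_lp <- logit(s$exposure_prob) - cf$coef_exposure * cf$prevalence +
      cf$coef_exposure * C
    X <- rbinom(n, 1L, expit(x_lp))
    m_shift <- cf$coef_mediator * C
    y_shift <- cf$coef_outcome * C
  } else {
    X <- rbinom(n, 1L, s$exposure_prob)
    m_shift <- 0; y_shift <- 0
  }
  med_lp <- gamma[1L] + gamma[2L] * X + m_shift
  if (s$case %in% c(2L, 4L)) {
    M <- rbinom(n, 1L, expit(med_lp))
    m_type <- "binary"
  } else {
    eps <- switch(s$error_model,
      normal = rnorm(n),
      heteroskedastic = {
        eta0 <- 1 - s$eta1 * s$exposure_prob  # E[sigma_x^2] = 1
        rnorm(n, sd = sqrt(eta0 + s$eta1 * X))
      },
      gamma = {
        k <- (2 / s$skew)^2; th <- s$skew / 2
        b <- rgamma(n, shape = k, scale = th)
        (b - k * th) / (sqrt(k) * th)
      })
    M <- med_lp + eps
    m_type <- "continuous"
  }
  out_lp <- beta[1L] + beta[2L] * X + beta[3L] * M + y_shift
  if (s$case >= 3L) {
    Y <- rbinom(n, 1L, expit(out_lp))
    y_type <- "binary"
  } else {
    Y <- out_lp + rnorm(n)
    y_type <- "continuous"
  }
  mediation_data(Y, X, M, w = if (has_c) matrix(C, ncol = 1,
                                                dimnames = list(NULL, "C")) else NULL,
                 y_type = y_type, m_type = m_type)
}

case_links <- function(case) {
  list(outcome = if (case >= 3L) "logit" else "identity",
       mediator = if (case %in% c(2L, 4L)) "logit" else "identity")
}

fit_theta_for_case <- function(data, case) {
  links <- case_links(case)
  of <- fit_outcome_model(data, links$outcome)
  mf <- fit_mediator_model(data, links$mediator)
  assemble_theta(of, mf, include_sigma2 = (case == 3L))
}

#' Run a replication study
#'
#' For each replication: generate a dataset, fit both models by their
#' estimating equations, and for each requested estimator variant compute
#' the NIE and MP point estimates, delta-method variances and 95% Wald
#' intervals (plus percentile-bootstrap intervals when `bootstrap_R` is
#' set). Replications where a fit fails to converge or shows separation are
#' excluded from the summaries and counted.
#'
#' Summary metrics per measure and variant, following the reference
#' operating-characteristic definitions:
#' * `median_pct_bias`: `median((est - true) / true) * 100`;
#' * `cr_delta`, `cr_boot`: percent of 95% CIs covering the truth;
#' * `vr`: median estimated variance / empirical variance of the point
#'   estimates;
#' * `cr_*_flag`: coverage outside the binomial band
#'   `95 +/- 1.96 sqrt(0.95 * 0.05 / B) * 100` with `B` successful reps.
#'
#' @param scenario A [simulation_scenario].
#' @param keep_replicates Attach the per-replication estimates as attribute
#'   `"replicates"`?
#' @param use_true_theta Diagnostic oracle mode: evaluate the measures at
#'   the true generating parameters instead of the fitted ones in every
#'   replication (median bias must then be zero, and the variance ratio is
#'   undefined because the point estimates have no empirical variance).
#' @return A `simulation_summary` data frame (one row per measure x
#'   variant) with attributes `scenario`, `params`, `n_failed`,
#'   `unreliable` (TRUE when more than 10% of replications failed).
#' @export
run_scenario <- function(scenario, keep_replicates = FALSE,
                         use_true_theta = FALSE) {
  s <- scenario
  params <- solve_scenario_params(s)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(s$seed)
  rep_seeds <- sample.int(2147483646L, s$reps)
  variants <- s$variants
  measures <- c("nie", "mp")
  truths <- c(nie = params$true_nie, mp = params$true_mp)
  # storage: [rep, variant, measure] for estimates and variances
  est <- array(NA_real_, c(s$reps, length(variants), 2L),
               dimnames = list(NULL, variants, measures))
  dvar <- est
  cover <- est
  cover_boot <- if (!is.null(s$bootstrap_R)) est else NULL
  n_failed <- 0L
  for (r in seq_len(s$reps)) {
    set.seed(rep_seeds[r])
    data <- generate_dataset(s, params)
    th <- if (use_true_theta) {
      theta_values(params$beta, params$gamma,
                   if (s$case == 3L) params$sigma2 else NULL)
    } else {
      tryCatch(fit_theta_for_case(data, s$case),
               prodmed_error = function(e) NULL)
    }
    if (is.null(th)) { n_failed <- n_failed + 1L; next }
    ok <- TRUE
    for (v in variants) {
      for (msr in measures) {
        mfun <- measure_function(th, s$case, msr, expression = v)
        dres <- tryCatch(delta_variance(mfun, th),
                         prodmed_error = function(e) NULL)
        if (is.null(dres)) { ok <- FALSE; break }
        est[r, v, msr] <- dres$estimate
        dvar[r, v, msr] <- dres$variance
        cover[r, v, msr] <-
          dres$ci[1L] <= truths[msr] && truths[msr] <= dres$ci[2L]
      }
      if (!ok) break
    }
    if (!ok) {
      est[r, , ] <- NA_real_; dvar[r, , ] <- NA_real_; cover[r, , ] <- NA_real_
      n_failed <- n_failed + 1L
      next
    }
    if (!is.null(s$bootstrap_R)) {
      for (v in variants) {
        estimator <- local({
          vv <- v; cs <- s$case
          function(d) {
            t2 <- fit_theta_for_case(d, cs)
            m <- mediation_measures(t2, cs, expression = vv)
            c(nie = m$nie, mp = m$mp)
          }
        })
        br <- tryCatch(
          percentile_bootstrap(data, estimator, R = s$bootstrap_R,
                               seed = rep_seeds[r]),
          prodmed_error = function(e) NULL)
        if (!is.null(br)) {
          for (msr in measures)
            cover_boot[r, v, msr] <-
              br$ci["lower", msr] <= truths[msr] &&
              truths[msr] <= br$ci["upper", msr]
        }
      }
    }
  }
  B_used <- s$reps - n_failed
  if (B_used == 0L)
    pm_computation_error("all replications failed")
  rows <- list()
  for (v in variants) for (msr in measures) {
    e <- est[, v, msr]; e <- e[!is.na(e)]
    dv <- dvar[, v, msr]; dv <- dv[!is.na(dv)]
    emp_var <- var(e)
    if (emp_var <= 0)
      pm_computation_error("empirical variance of point estimates is zero; variance ratio undefined")
    cr_d <- 100 * mean(cover[, v, msr], na.rm = TRUE)
    cr_b <- if (!is.null(cover_boot)) {
      cb <- cover_boot[, v, msr]
      if (all(is.na(cb))) NA_real_ else 100 * mean(cb, na.rm = TRUE)
    } else NA_real_
    band <- 1.96 * sqrt(0.95 * 0.05 / B_used) * 100
    rows[[length(rows) + 1L]] <- data.frame(
      case = s$case, n = s$n, te = s$te, mp = s$mp,
      measure = toupper(msr), variant = v, truth = truths[msr],
      median_pct_bias = median((e - truths[msr]) / truths[msr]) * 100,
      cr_delta = cr_d,
      cr_boot = cr_b,
      vr = median(dv) / emp_var,
      n_failed = n_failed,
      cr_delta_flag = abs(cr_d - 95) > band,
      cr_boot_flag = if (is.na(cr_b)) NA else abs(cr_b - 95) > band,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scenario") <- s
  attr(out, "params") <- params
  attr(out, "n_failed") <- n_failed
  attr(out, "unreliable") <- n_failed > 0.1 * s$reps
  if (keep_replicates)
    attr(out, "replicates") <- list(estimates = est, variances = dvar)
  class(out) <- c("simulation_summary", class(out))
  out
}

#' Sweep the baseline outcome prevalence
#'
#' Re-solves the outcome coefficients at each baseline prevalence and runs
#' the scenario, so exact and rare-outcome-approximate estimators can be
#' compared side by side as the outcome becomes common.
#'
#' @param base_scenario A binary-outcome [simulation_scenario] (case 3 or 4).
#' @param prevalences Numeric vector of baseline outcome prevalences.
#' @return Named list of `simulation_summary` objects, one per prevalence.
#' @export
prevalence_sweep <- function(base_scenario, prevalences) {
  if (!base_scenario$case %in% 3:4)
    pm_validation_error("prevalence sweep applies to binary-outcome cases (3, 4)")
  out <- lapply(prevalences, function(p) {
    s <- base_scenario
    s$outcome_prev <- p
    run_scenario(s)
  })
  names(out) <- as.character(prevalences)
  out
}
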