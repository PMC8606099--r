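# Generator calibration solvers, the data-generating processes, and the
# replication-study driver.

test_that("correlation-calibrated slopes hit their targets", {
  g1c <- solve_gamma1_for_correlation("continuous", 0.2)
  expect_equal(round(g1c, 3), 0.408)
  # round-trip: implied correlation equals the target
  expect_equal(0.5 * g1c / sqrt(0.25 * g1c^2 + 1), 0.2, tolerance = 1e-12)
  g1b <- solve_gamma1_for_correlation("binary", 0.2, baseline_prev = 0.2)
  p0 <- 0.2; p1 <- plogis(qlogis(p0) + g1b); pbar <- (p0 + p1) / 2
  expect_equal(0.5 * (p1 - p0) / sqrt(pbar * (1 - pbar)), 0.2,
               tolerance = 1e-10)
  expect_identical(solve_gamma1_for_correlation("continuous", 0), 0)
  expect_identical(solve_gamma1_for_correlation("binary", 0,
                                                baseline_prev = 0.2), 0)
  # unattainable binary correlation reports the feasible range
  expect_error(solve_gamma1_for_correlation("binary", 0.95,
                                            baseline_prev = 0.2),
               "feasible range", class = "prodmed_validation_error")
})

test_that("intercepts are the logit of the baseline prevalence", {
  expect_identical(intercept_from_prevalence(0.5), 0)
  expect_equal(intercept_from_prevalence(0.2), log(0.25))
  expect_equal(intercept_from_prevalence(0.03), qlogis(0.03))
  expect_error(intercept_from_prevalence(0), class = "prodmed_validation_error")
  expect_error(intercept_from_prevalence(1), class = "prodmed_validation_error")
})

test_that("continuous-outcome coefficient solvers invert the measures", {
  b <- solve_linear_outcome_params(1, te = 1, mp = 0.5, gamma1 = 0.408)
  expect_equal(unname(b), c(0.5, 0.5 / 0.408), tolerance = 1e-12)
  expect_equal(unname(solve_linear_outcome_params(1, te = 0.7, mp = 0,
                                                  gamma1 = 0.408)),
               c(0.7, 0))
  expect_error(solve_linear_outcome_params(1, te = 1, mp = 0.3, gamma1 = 0),
               class = "prodmed_validation_error")
  # case 2 round-trip through the measures
  g0 <- qlogis(0.2); g1 <- 0.903
  b2 <- solve_linear_outcome_params(2, te = 0.5, mp = 0.2, gamma0 = g0,
                                    gamma1 = g1)
  th <- theta_fixture(beta = c(0, b2), gamma = c(g0, g1))
  m <- mediation_measures(th, 2)
  expect_equal(m$te, 0.5, tolerance = 1e-12)
  expect_equal(m$mp, 0.2, tolerance = 1e-12)
})

test_that("binary-outcome solvers hit the exact targets and are monotone", {
  g1 <- solve_gamma1_for_correlation("continuous", 0.2)
  b0 <- intercept_from_prevalence(0.03)
  tes <- log(c(1.2, 1.5, 2))
  solved_b1 <- numeric(length(tes))
  for (i in seq_along(tes)) {
    b <- solve_logistic_outcome_params(3, tes[i], 0.2, b0, c(0, g1), 1)
    solved_b1[i] <- b[1]
    th <- theta_fixture(c(b0, b), c(0, g1), sigma2 = 1)
    m <- mediation_measures(th, 3)
    expect_equal(m$nie, 0.2 * tes[i], tolerance = 1e-8)
    expect_equal(m$nde, 0.8 * tes[i], tolerance = 1e-8)
  }
  expect_true(all(diff(solved_b1) > 0))  # beta1 increasing in TE at fixed MP
  # degenerate MP = 0 system: beta2 = 0 and beta1 solves the NDE equation
  bz <- solve_logistic_outcome_params(4, log(1.5), 0,
                                      intercept_from_prevalence(0.03),
                                      c(qlogis(0.2), 0.903))
  expect_identical(unname(bz[2]), 0)
  thz <- theta_fixture(c(intercept_from_prevalence(0.03), bz),
                       c(qlogis(0.2), 0.903))
  expect_equal(mediation_measures(thz, 4)$te, log(1.5), tolerance = 1e-8)
})

test_that("generated data match the calibrated moments", {
  set.seed(51)
  s1 <- simulation_scenario(1, 200000, te = 0.5, mp = 0.2, reps = 1, seed = 1)
  p1 <- solve_scenario_params(s1)
  d1 <- generate_dataset(s1, p1)
  expect_lt(abs(cor(d1$x, d1$m) - 0.2), 0.005)
  s4 <- simulation_scenario(4, 500000, te = log(1.5), mp = 0.2, reps = 1,
                            seed = 1)
  p4 <- solve_scenario_params(s4)
  d4 <- generate_dataset(s4, p4)
  base <- d4$y[d4$x == 0 & d4$m == 0]
  expect_lt(abs(mean(base) - 0.03), 0.002)
  # heteroskedastic mediator: exposed/unexposed variance ratio = 3 at eta1 = 1
  sh <- simulation_scenario(3, 200000, te = log(1.5), mp = 0.2, reps = 1,
                            seed = 1, error_model = "heteroskedastic", eta1 = 1)
  ph <- solve_scenario_params(sh)
  dh <- generate_dataset(sh, ph)
  rres <- dh$m - (ph$gamma[1] + ph$gamma[2] * dh$x)
  expect_lt(abs(var(rres[dh$x == 1]) / var(rres[dh$x == 0]) - 3), 0.1)
  # standardized gamma errors: mean 0, variance 1, skewness ~ s
  sg <- simulation_scenario(3, 400000, te = log(1.5), mp = 0.2, reps = 1,
                            seed = 1, error_model = "gamma", skew = 2)
  pg <- solve_scenario_params(sg)
  dg <- generate_dataset(sg, pg)
  eg <- dg$m - (pg$gamma[1] + pg$gamma[2] * dg$x)
  expect_lt(abs(mean(eg)), 0.01)
  expect_lt(abs(var(eg) - 1), 0.02)
  expect_lt(abs(mean(eg^3) - 2), 0.15)
  # binary confounder is carried as a covariate and shifts the models
  sc <- simulation_scenario(1, 50000, te = 0.5, mp = 0.2, reps = 1, seed = 1,
                            confounder = list(prevalence = 0.3,
                                              coef_exposure = 0.5,
                                              coef_mediator = 0.4,
                                              coef_outcome = 0.6))
  pc <- solve_scenario_params(sc)
  dc <- generate_dataset(sc, pc)
  expect_identical(colnames(dc$w), "C")
  expect_gt(cor(dc$w[, 1], dc$m), 0.05)
})

test_that("solver/measure round-trip holds for every case", {
  for (case in 1:4) {
    s <- simulation_scenario(case, 1000,
                             te = if (case >= 3) log(1.5) else 0.5,
                             mp = 0.2, reps = 1, seed = 1)
    p <- solve_scenario_params(s)
    th <- theta_fixture(p$beta, p$gamma, if (case == 3) p$sigma2 else NULL)
    m <- mediation_measures(th, case, expression = "exact")
    expect_equal(m$nie, p$true_nie, tolerance = 1e-8)
    expect_equal(m$mp, s$mp, tolerance = 1e-8)
  }
})

test_that("run_scenario is deterministic and reports all metric fields", {
  s <- simulation_scenario(1, 150, te = 0.5, mp = 0.2, reps = 60, seed = 77,
                           bootstrap_R = 120)
  r1 <- run_scenario(s)
  r2 <- run_scenario(s)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(r1$measure, c("NIE", "MP"))
  expect_true(all(is.finite(r1$median_pct_bias)))
  expect_true(all(r1$cr_delta >= 0 & r1$cr_delta <= 100))
  expect_true(all(r1$cr_boot >= 0 & r1$cr_boot <= 100))
  expect_true(all(is.finite(r1$vr) & r1$vr >= 0))
  expect_true(is.logical(r1$cr_delta_flag))
})

test_that("true-parameter oracle gives zero bias and an undefined VR", {
  s <- simulation_scenario(2, 300, te = 0.5, mp = 0.2, reps = 30, seed = 5)
  expect_error(run_scenario(s, use_true_theta = TRUE),
               "empirical variance", class = "prodmed_computation_error")
})

test_that("prevalence sweep re-solves per prevalence", {
  s <- simulation_scenario(4, 800, te = log(2), mp = 0.5, reps = 25, seed = 9)
  sweep <- prevalence_sweep(s, c(0.03, 0.2))
  expect_length(sweep, 2L)
  p_low <- attr(sweep[["0.03"]], "params")
  p_high <- attr(sweep[["0.2"]], "params")
  expect_false(isTRUE(all.equal(p_low$beta, p_high$beta)))
  # both hit the same exact truths by construction
  expect_equal(p_low$true_nie, p_high$true_nie)
  expect_error(prevalence_sweep(
    simulation_scenario(1, 500, 0.5, 0.2, reps = 5, seed = 1), 0.1),
    class = "prodmed_validation_error")
})

test_that("case-3 exact estimator is robust to mediator error misspecification", {
  # scaled-down robustness check (fewer replications than the reference
  # design); compares median percent bias across error models at matched
  # settings
  base <- simulation_scenario(3, 20000, te = log(2), mp = 0.2, reps = 300,
                              seed = 13, variants = "exact")
  bias_of <- function(s) {
    r <- run_scenario(s)
    r$median_pct_bias[r$measure == "NIE" & r$variant == "exact"]
  }
  b_norm <- bias_of(base)
  het <- base; het$error_model <- "heteroskedastic"; het$eta1 <- 1
  gam <- base; gam$error_model <- "gamma"; gam$skew <- 2
  expect_lt(abs(bias_of(het) - b_norm), 3)
  expect_lt(abs(bias_of(gam) - b_norm), 3)
})
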