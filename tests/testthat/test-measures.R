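# Mediation measure expressions for the four data types, the quadrature
# kernel, the binary-mediator enumeration oracle, and their invariants.

test_that("exp_linear evaluates and guards the exponentiated linear predictor", {
  expect_equal(exp_linear(c(0, 0), x = 3.7), 1)
  expect_equal(exp_linear(c(0, 0.903), x = 1), exp(0.903))
  expect_equal(exp_linear(c(0.5, 1, 2), x = 1, w = 0.25), exp(2))
  # monotone increasing in x for positive slope
  vals <- vapply(c(-1, 0, 1, 2), function(x) exp_linear(c(0.2, 0.9), x),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_warning(exp_linear(c(0, 1000), x = 1), "clipped")
  expect_error(exp_linear(c(0, 1), x = 1, w = c(1, 2)), "length")
})

test_that("case 1 measures follow the product formulas", {
  th <- theta_fixture(beta = c(0, 0.5, 0.5 / 0.408), gamma = c(0, 0.408))
  m <- mediation_measures(th, 1)
  expect_equal(m$nie, 0.5, tolerance = 1e-12)
  expect_equal(m$nde, 0.5, tolerance = 1e-12)
  expect_equal(m$mp, 0.5, tolerance = 1e-12)
  expect_equal(m$scale, "difference")
  # MP invariant to the contrast width (cancels in the ratio)
  m2 <- mediation_measures(th, 1, x_star = 1, x_new = 4)
  expect_equal(m2$mp, m$mp, tolerance = 1e-12)
  expect_equal(m2$nie, 3 * m$nie, tolerance = 1e-12)
  # null contrast: all effects zero, MP flagged undefined
  m0 <- mediation_measures(th, 1, x_star = 1, x_new = 1)
  expect_identical(c(m0$nie, m0$nde, m0$te), c(0, 0, 0))
  expect_false(m0$mp_defined)
})

test_that("case 2 measures use the mediator prevalence contrast", {
  g0 <- qlogis(0.2)
  th <- theta_fixture(beta = c(0, 0.3, 0.7), gamma = c(g0, 0.903))
  m <- mediation_measures(th, 2)
  expect_equal(m$nie, 0.7 * (plogis(g0 + 0.903) - 0.2), tolerance = 1e-12)
  expect_equal(m$nde, 0.3)
  th0 <- theta_fixture(beta = c(0, 0.3, 0), gamma = c(g0, 0.903))
  expect_equal(mediation_measures(th0, 2)$nie, 0)
  expect_equal(mediation_measures(th, 2, x_star = 2, x_new = 2)$nie, 0)
})

test_that("quadrature ratio matches independent oracles", {
  # beta2 = 0: the two integrals coincide
  expect_identical(ghq_logistic_normal_ratio(0.3, 0, 1, 2), 1)
  # denominator -> 1 limit: lognormal moment identity E[exp(b2 M)]
  b2 <- 0.6; mu <- 0.4; s2 <- 1.3
  expect_equal(ghq_logistic_normal_ratio(-30, b2, mu, s2),
               exp(b2 * mu + b2^2 * s2 / 2), tolerance = 1e-8)
  # randomized draws against adaptive quadrature, and node-doubling stability
  set.seed(21)
  for (i in 1:20) {
    bl <- runif(1, -4, 2); b2 <- runif(1, -1.5, 1.5)
    mu <- runif(1, -1, 1); s2 <- runif(1, 0.3, 2)
    r40 <- ghq_logistic_normal_ratio(bl, b2, mu, s2, nodes = 40)
    r80 <- ghq_logistic_normal_ratio(bl, b2, mu, s2, nodes = 80)
    expect_equal(r40, adaptive_logistic_normal_ratio(bl, b2, mu, s2),
                 tolerance = 1e-8)
    expect_equal(r40, r80, tolerance = 1e-8)
  }
  expect_error(ghq_logistic_normal_ratio(0, 1, 0, -1), "positive",
               class = "prodmed_validation_error")
})

test_that("case 3 exact measures behave in the known limits", {
  th0 <- theta_fixture(beta = c(-2, 0.4, 0), gamma = c(0, 0.408), sigma2 = 1)
  expect_equal(mediation_measures(th0, 3)$nie, 0, tolerance = 1e-14)
  # rare outcome: exact approaches the product approximation
  thr <- theta_fixture(beta = c(-10, 0.3, 0.5), gamma = c(0, 0.408), sigma2 = 1)
  ex <- mediation_measures(thr, 3, expression = "exact")
  ap <- mediation_measures(thr, 3, expression = "approx")
  expect_lt(abs(ex$nie - ap$nie), 1e-3)
  # vanishing mediator variance: logit contrasts collapse to the product form
  ths <- theta_fixture(beta = c(-1, 0.3, 0.5), gamma = c(0, 0.408),
                       sigma2 = 1e-8)
  exs <- mediation_measures(ths, 3, expression = "exact")
  expect_equal(exs$nie, 0.5 * 0.408, tolerance = 1e-4)
})

test_that("case 3 probit approximation matches a direct evaluation", {
  beta <- c(-0.2, 0.3, 0.6); gamma <- c(0.1, 0.408); s2 <- 1.2
  th <- theta_fixture(beta, gamma, sigma2 = s2)
  m <- mediation_measures(th, 3, expression = "probit")
  s <- 1 / 1.6
  a <- function(xo, xm)
    (s * (beta[1] + beta[2] * xo) + s * beta[3] * (gamma[1] + gamma[2] * xm)) /
      sqrt(1 + s^2 * beta[3]^2 * s2)
  lf <- function(z) qlogis(pnorm(z))
  expect_equal(m$nie, lf(a(1, 1)) - lf(a(1, 0)), tolerance = 1e-12)
  expect_equal(m$nde, lf(a(1, 0)) - lf(a(0, 0)), tolerance = 1e-12)
  # probit is a case-3-only variant
  expect_error(mediation_measures(th, 4, expression = "probit"),
               class = "prodmed_validation_error")
  # near 50% baseline prevalence the probit and exact NIE are close
  expect_lt(abs(m$nie - mediation_measures(th, 3)$nie),
            0.02 * abs(mediation_measures(th, 3)$nie) + 1e-4)
})

test_that("case 4 enumeration matches hand-expanded arithmetic", {
  th <- theta_fixture(beta = c(-3.476, 0.4, 0.8), gamma = c(-1.386, 0.903))
  # direct two-term probability sum, written out independently
  pm0 <- exp(-1.386) / (1 + exp(-1.386))
  py1 <- exp(-3.476 + 0.4 + 0.8) / (1 + exp(-3.476 + 0.4 + 0.8))
  py0 <- exp(-3.476 + 0.4) / (1 + exp(-3.476 + 0.4))
  p <- py1 * pm0 + py0 * (1 - pm0)
  expect_equal(enumerate_case4_logit_potential(th, 1, 0), log(p / (1 - p)),
               tolerance = 1e-12)
  # beta2 = 0 or gamma1 = 0: mediator arm is irrelevant
  thb <- theta_fixture(beta = c(-2, 0.4, 0), gamma = c(-1.386, 0.903))
  expect_equal(enumerate_case4_logit_potential(thb, 1, 0),
               enumerate_case4_logit_potential(thb, 1, 1), tolerance = 1e-14)
  thg <- theta_fixture(beta = c(-2, 0.4, 0.8), gamma = c(-1.386, 0))
  expect_equal(enumerate_case4_logit_potential(thg, 1, 0),
               enumerate_case4_logit_potential(thg, 1, 1), tolerance = 1e-14)
})

test_that("case 4 exact equals the verified closed forms on random draws", {
  set.seed(22)
  for (i in 1:25) {
    th <- random_theta4()
    ex <- mediation_measures(th, 4, expression = "exact")
    expect_equal(ex$nie,
                 prodmed:::case4_closed_nie(th, 0, 1), tolerance = 1e-10)
    expect_equal(ex$nde,
                 prodmed:::case4_closed_nde(th, 0, 1), tolerance = 1e-10)
  }
  # beta2 = 0: no indirect path, TE reduces to beta1 dx
  th0 <- theta_fixture(beta = c(-1.5, 0.4, 0), gamma = c(-1, 0.9))
  m0 <- mediation_measures(th0, 4, expression = "exact")
  expect_equal(m0$nie, 0, tolerance = 1e-14)
  expect_equal(m0$te, 0.4, tolerance = 1e-12)
  # rare outcome: exact converges to the displayed approximation
  thr <- theta_fixture(beta = c(-30, 0.4, 0.8), gamma = c(-1.386, 0.903))
  exr <- mediation_measures(thr, 4, expression = "exact")
  apr <- mediation_measures(thr, 4, expression = "approx")
  expect_lt(abs(exr$nie - apr$nie), 1e-8)
  expect_lt(abs(exr$nde - apr$nde), 1e-8)
})

test_that("mp_from is the unclamped ratio with a guarded denominator", {
  expect_equal(mp_from(0.2, 0.2), 0.5)
  expect_equal(mp_from(0, 0.7), 0)
  expect_equal(mp_from(0.3, -0.1), 1.5)  # sign-discordant, no clamping
  expect_error(mp_from(1e-13, -1e-13), "undefined",
               class = "prodmed_computation_error")
})

test_that("decomposition identities hold across cases and expressions", {
  set.seed(23)
  cases <- list(
    list(case = 1, th = theta_fixture(c(0.2, 0.5, 1.1), c(0.1, 0.408))),
    list(case = 2, th = theta_fixture(c(0.2, 0.5, 1.1), c(-1.386, 0.903))),
    list(case = 3, th = theta_fixture(c(-2, 0.4, 0.7), c(0.1, 0.408),
                                      sigma2 = 1.1)),
    list(case = 4, th = theta_fixture(c(-2, 0.4, 0.7), c(-1.386, 0.903))))
  for (cs in cases) {
    exprs <- switch(as.character(cs$case), "1" = , "2" = "exact",
                    "3" = c("exact", "approx", "probit"),
                    "4" = c("exact", "approx"))
    for (ex in exprs) {
      m <- mediation_measures(cs$th, cs$case, x_star = -0.5, x_new = 1.5,
                              expression = ex)
      expect_equal(m$te, m$nie + m$nde, tolerance = 1e-12)
      expect_equal(m$mp * m$te, m$nie, tolerance = 1e-12)
      mnull <- mediation_measures(cs$th, cs$case, x_star = 0.7, x_new = 0.7,
                                  expression = ex)
      expect_equal(c(mnull$nie, mnull$nde, mnull$te), c(0, 0, 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("covariate dependence matches the expression catalogue", {
  # one covariate in each model, nonzero coefficients
  th <- theta_fixture(beta = c(-2, 0.4, 0.7, 0.5), gamma = c(0.1, 0.408, -0.6))
  th$sigma2 <- 1
  nie_w <- function(case, ex, w)
    mediation_measures(th, case, w_out = w, w_med = w, expression = ex)$nie
  # exact binary-outcome expressions vary with w
  expect_false(isTRUE(all.equal(nie_w(3, "exact", 0), nie_w(3, "exact", 1))))
  expect_false(isTRUE(all.equal(nie_w(4, "exact", 0), nie_w(4, "exact", 1))))
  # the case-3 rare-outcome approximation is w-free
  expect_identical(nie_w(3, "approx", 0), nie_w(3, "approx", 1))
  # case 2 depends on w through the mediator model
  th2 <- theta_fixture(beta = c(0, 0.4, 0.7, 0.5), gamma = c(0.1, 0.9, -0.6))
  expect_false(isTRUE(all.equal(
    mediation_measures(th2, 2, w_out = 0, w_med = 0)$nie,
    mediation_measures(th2, 2, w_out = 1, w_med = 1)$nie)))
  # dimension mismatch is rejected
  expect_error(mediation_measures(th, 3, w_out = c(1, 2)),
               class = "prodmed_validation_error")
})
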