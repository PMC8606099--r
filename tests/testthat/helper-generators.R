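# Shared fixture builders. Everything is generated in code at test time.

# Continuous outcome / continuous mediator draw.
gen_case1 <- function(n, beta = c(0, 0.5, 1.2255), gamma = c(0, 0.408),
                      sd_y = 1, sd_m = 1) {
  x <- rbinom(n, 1, 0.5)
  m <- gamma[1] + gamma[2] * x + rnorm(n, sd = sd_m)
  y <- beta[1] + beta[2] * x + beta[3] * m + rnorm(n, sd = sd_y)
  mediation_data(y, x, m, y_type = "continuous", m_type = "continuous")
}

# Binary outcome / continuous mediator draw.
gen_case3 <- function(n, beta, gamma = c(0, 0.408)) {
  x <- rbinom(n, 1, 0.5)
  m <- gamma[1] + gamma[2] * x + rnorm(n)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x + beta[3] * m))
  mediation_data(y, x, m, y_type = "binary", m_type = "continuous")
}

# Binary outcome / binary mediator draw.
gen_case4 <- function(n, beta, gamma = c(qlogis(0.2), 0.903)) {
  x <- rbinom(n, 1, 0.5)
  m <- rbinom(n, 1, plogis(gamma[1] + gamma[2] * x))
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x + beta[3] * m))
  mediation_data(y, x, m, y_type = "binary", m_type = "binary")
}

# Parameter-only theta (no sampling uncertainty) for measure-level tests.
theta_fixture <- function(beta, gamma, sigma2 = NULL) {
  prodmed:::theta_values(beta, gamma, sigma2)
}

# Random moderate parameter draws for property-style loops.
random_theta4 <- function() {
  theta_fixture(beta = c(runif(1, -3, 1), runif(1, -1, 1), runif(1, -1.5, 1.5)),
                gamma = c(runif(1, -2, 1), runif(1, -1.5, 1.5)))
}

# Independent adaptive-quadrature oracle for the logistic-normal ratio.
adaptive_logistic_normal_ratio <- function(beta_lin, beta2, mu, sigma2) {
  sd <- sqrt(sigma2)
  num <- integrate(function(m) exp(beta2 * m) * dnorm(m, mu, sd) /
                     (1 + exp(beta_lin + beta2 * m)),
                   mu - 10 * sd, mu + 10 * sd, rel.tol = 1e-12)$value
  den <- integrate(function(m) dnorm(m, mu, sd) /
                     (1 + exp(beta_lin + beta2 * m)),
                   mu - 10 * sd, mu + 10 * sd, rel.tol = 1e-12)$value
  num / den
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# Elementwise covariance comparison normalized by the diagonal scale,
# so near-zero off-diagonal entries do not blow up a relative tolerance.
cov_rel_diff <- function(A, B) {
  s <- sqrt(diag(B))
  max(abs(A - B) / outer(s, s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
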