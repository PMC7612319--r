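# Independent oracles used to freeze expected values in the tests.

# Closed-form EVSI for the Beta-binomial family: with p ~ Beta(a, b) and a
# binomial study of size n, the expected posterior variance is known and
# EVSI = V0 * n / (a + b + n), V0 = prior variance.
beta_binom_evsi <- function(a, b, n) {
  v0 <- a * b / ((a + b)^2 * (a + b + 1))
  v0 * n / (a + b + n)
}

# Brute-force two-level Monte Carlo EVPPI for the linear-Gaussian
# estimation problem y = theta1 + theta2, theta_i ~ N(0,1), phi = theta1.
nested_mc_evppi_est <- function(n_outer = 500, n_inner = 500) {
  inner_means <- vapply(rnorm(n_outer), function(t1)
    mean(t1 + rnorm(n_inner)), numeric(1))
  est <- stats::var(inner_means)
  list(value = est, se = est * sqrt(2 / (n_outer - 1)))
}

# Brute-force two-level Monte Carlo EVPPI for the decision problem
# NB1 = 0, NB2 = theta1 + theta2, phi = theta1 (inner expectation of NB2
# given theta1 is analytically theta1, but is estimated by simulation so
# the oracle stays independent of that knowledge).
nested_mc_evppi_dec <- function(n_outer = 500, n_inner = 500) {
  perfect <- vapply(rnorm(n_outer), function(t1)
    max(0, mean(t1 + rnorm(n_inner))), numeric(1))
  grand <- mean(rnorm(n_outer * n_inner) + rnorm(n_outer * n_inner))
  est <- mean(perfect) - max(0, grand)
  list(value = est, se = stats::sd(perfect) / sqrt(n_outer))
}

expect_voi <- function(est) {
  expect_s3_class(est, "voi_estimate")
  expect_gte(est$value, 0)
}
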