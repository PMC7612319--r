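test_that("debias shifts on the logit scale and preserves (0, 1) support", {
  p <- c(0.2, 0.5, 0.9)
  expect_equal(debias(p, bias_model(0)), p)             # sigma = 0: identity
  expect_equal(debias(rep(0.5, 3), bias_model(0, shift = log(1.5))),
               rep(0.6, 3))                             # expit(ln 1.5) = 0.6
  set.seed(61)
  pa <- rbeta(1e5, 5.7, 8.9)
  p0 <- debias(pa, bias_model(0.7), seed = 2)
  expect_true(all(p0 > 0 & p0 < 1))
  # independent additive variance on the logit scale
  lv <- var(qlogis(p0))
  expect_equal(lv, var(qlogis(pa)) + 0.7^2, tolerance = 0.02 * lv)
  expect_error(debias(c(0, 0.5), bias_model(1)), "strictly in")
})

test_that("solve_bias_sd matches a brute-force grid oracle and round-trips", {
  pa_fun <- function(n) rbeta(n, 5.7, 8.9)
  sig <- solve_bias_sd(pa_fun, ratio_target = 1.2, prob = 0.9, seed = 3)
  # independent large-sample grid search over sigma
  set.seed(99)
  pa <- pa_fun(1e6); z <- rnorm(1e6)
  grid <- seq(0.5 * sig, 1.5 * sig, length.out = 61)
  q90 <- vapply(grid, function(s)
    unname(quantile(plogis(qlogis(pa) + s * z) / pa, 0.9)), numeric(1))
  oracle <- grid[which.min(abs(q90 - 1.2))]
  expect_equal(sig, oracle, tolerance = 0.02)
  # round trip: the solved sigma reproduces the target quantile
  p0 <- plogis(qlogis(pa) + sig * z)
  expect_equal(unname(quantile(p0 / pa, 0.9)), 1.2, tolerance = 0.005)
  # tiny targets need tiny bias
  expect_lt(solve_bias_sd(pa_fun, 1.001, seed = 3), 0.01)
  # monotone in the elicited ratio
  expect_gt(solve_bias_sd(pa_fun, 1.5, seed = 3), sig)
  expect_error(solve_bias_sd(pa_fun, 0.9), "exceed 1")
})

test_that("hierarchical evidence builder derives logit scales from intervals", {
  ev <- hierarchical_evidence(c(0.3, 0.5), lower = c(0.2, 0.4),
                              upper = c(0.42, 0.6))
  expect_equal(ev$s,
               (qlogis(c(0.42, 0.6)) - qlogis(c(0.2, 0.4))) / (2 * qnorm(0.975)))
  expect_error(hierarchical_evidence(c(0.3, 1.2), s = c(0.1, 0.1)),
               "strictly in")
  expect_error(hierarchical_evidence(0.3, lower = 0.5, upper = 0.4),
               "lower < upper")
})

test_that("hierarchical posterior concentrates for concordant areas and
           widens with heterogeneity", {
  skip_if_not_installed("rjags")
  # identical precise estimates: posterior for a new area sits near them
  ev_same <- hierarchical_evidence(rep(0.4, 5), s = rep(0.02, 5))
  p_same <- hierarchical_target(ev_same, R = 4000, seed = 11)
  expect_equal(median(p_same), 0.4, tolerance = 0.03)
  # spread ordering: heterogeneous evidence leaves more uncertainty
  p_hi <- hierarchical_target(synthetic_areas(6, "high", seed = 3),
                              R = 4000, seed = 12)
  p_lo <- hierarchical_target(synthetic_areas(6, "low", seed = 3),
                              R = 4000, seed = 12)
  expect_gt(sd(p_hi), sd(p_lo))
  # single area runs, dominated by the hyperpriors
  p_one <- hierarchical_target(hierarchical_evidence(0.4, s = 0.1),
                               R = 2000, seed = 13)
  expect_true(all(p_one > 0 & p_one < 1))
})

test_that("hierarchical model recovers known hyperparameters", {
  skip_if_not_installed("rjags")
  set.seed(62)
  M <- 20
  mu_true <- -0.4; sig_true <- 0.5
  lpi <- rnorm(M, mu_true, sig_true)
  s <- rep(0.05, M)
  ev <- hierarchical_evidence(plogis(rnorm(M, lpi, s)), s = s)
  p0 <- hierarchical_target(ev, R = 4000, seed = 14)
  dg <- attr(p0, "diagnostics")
  expect_lt(abs(dg$mu_mean - mu_true), 3 * dg$mu_sd)
  expect_lt(abs(dg$sigma_mean - sig_true), 3 * dg$sigma_sd)
  expect_true(all(dg$rhat < 1.05))
})
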