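test_that("scenario concentration follows g1 = mu(pi D + 1 - pi)", {
  expect_equal(scenario_concentration(20, 0.4, 0.5), 16)
  expect_equal(scenario_concentration(12.3, 0.7, 1), 12.3)
  expect_equal(scenario_concentration(12.3, 0, 0.2), 12.3)
  expect_error(scenario_concentration(-1, 0.5, 0.5), "positive")
  expect_error(scenario_concentration(10, 1.5, 0.5), "0, 1")
})

test_that("dose-response curve is piecewise with threshold and asymptote", {
  expect_equal(dose_response(3, 1, 0.1, 1, tau = 5), 1)
  expect_equal(dose_response(c(10, 20, 30), 0, 0.1, 1, 5), rep(1, 3))
  expect_equal(dose_response(15, 1, 0.1, 1, 5), 1 + (1 - exp(-1)),
               tolerance = 1e-12)
  x <- seq(0, 60, by = 0.5)
  rr <- dose_response(x, 0.6, 0.06, 1.2, 4)
  expect_true(all(rr >= 1 & rr <= 1.6))
  expect_true(all(diff(rr) >= 0))
  expect_error(dose_response(10, 1, -1, 1, 0), "invalid")
})

test_that("cases averted composes the concentration and risk functions", {
  cfg <- health_model_config(D = 1, I0 = 1000)
  th <- data.frame(mu = 20, pi = 0.4, alpha = 1, beta = 0.1,
                   gamma = 1, tau = 5)
  expect_equal(cases_averted(th, cfg), 0)  # scenario = baseline
  cfg2 <- health_model_config(D = 0.5, I0 = 18530)
  expected <- 18530 * (1 - dose_response(16, 1, 0.1, 1, 5) /
                           dose_response(20, 1, 0.1, 1, 5))
  expect_equal(cases_averted(th, cfg2), expected, tolerance = 1e-12)
  expect_true(expected > 0)
})

test_that("input sampler reproduces the stated marginal distributions", {
  cfg <- health_model_config()
  set.seed(51)
  mu <- stats::rlnorm(1e5, cfg$mu_meanlog, cfg$mu_sdlog)
  pb <- stats::rbeta(1e5, cfg$pi_shape1, cfg$pi_shape2)
  # Beta(5.7, 8.9) mean = 5.7/14.6 ~ 0.39; lognormal(2.7, 0.3) 95% limits
  expect_equal(mean(pb), 5.7 / 14.6, tolerance = 0.005)
  expect_equal(unname(quantile(mu, c(0.025, 0.975))),
               exp(2.7 + c(-1, 1) * qnorm(0.975) * 0.3), tolerance = 0.02)
  inp1 <- sample_inputs(cfg, R = 60, seed = 8)
  inp2 <- sample_inputs(cfg, R = 60, seed = 8)
  expect_identical(inp1, inp2)
  expect_named(inp1, c("mu", "pi", "alpha", "beta", "gamma", "tau"))
})

test_that("dose-response sampling collapses without perturbation and
           recovers known parameters", {
  tab0 <- synthetic_dr_table(se_log_rr = 1e-12)
  d0 <- generate_dr_sample(tab0, R = 20, seed = 4)
  expect_lt(max(apply(d0, 2, function(v) diff(range(v)) / abs(mean(v)))),
            1e-3)
  # simulate-then-recover at small published SE
  d <- generate_dr_sample(synthetic_dr_table(se_log_rr = 0.02),
                          R = 2000, seed = 7)
  med <- apply(d, 2, median)
  truth <- c(alpha = 0.6, beta = 0.06, gamma = 1.2, tau = 4)
  expect_true(all(abs(med - truth) / truth < 0.10))
  expect_gte(attr(d, "convergence_rate"), 0.9)
  # every sampled curve respects 1 <= g2 <= 1 + alpha
  x <- seq(0, 40, by = 2)
  ok <- vapply(seq_len(50), function(i) {
    rr <- dose_response(x, d$alpha[i], d$beta[i], d$gamma[i], d$tau[i])
    all(rr >= 1 & rr <= 1 + d$alpha[i] + 1e-12)
  }, logical(1))
  expect_true(all(ok))
  expect_error(generate_dr_sample(synthetic_dr_table()[1:3, ], 10),
               "at least 5")
})

test_that("strength extremes pick the nearest-rank order statistics of rho", {
  set.seed(52)
  d <- data.frame(alpha = runif(1000, 0.1, 1), beta = runif(1000, 0.02, 0.2),
                  gamma = runif(1000, 0.8, 1.5), tau = runif(1000, 0, 4))
  ext <- strength_extremes(d, x_low = 10, x_high = 15)
  rho <- dose_response(10, d$alpha, d$beta, d$gamma, d$tau) /
         dose_response(15, d$alpha, d$beta, d$gamma, d$tau)
  expect_true(all(rho <= 1))              # curves are nondecreasing in x
  ord <- order(rho)
  expect_equal(ext$lower,
               unlist(d[ord[25], c("alpha", "beta", "gamma", "tau")]))
  expect_equal(ext$upper,
               unlist(d[ord[975], c("alpha", "beta", "gamma", "tau")]))
  flat <- data.frame(alpha = rep(0, 200), beta = 0.1, gamma = 1, tau = 2)
  expect_warning(extf <- strength_extremes(flat), "identical pair")
  expect_equal(extf$lower, extf$upper)
})

test_that("run_example composes the model deterministically", {
  cfg <- health_model_config()
  ex1 <- run_example(cfg, R = 50, seed = 6, mode = "estimation")
  ex2 <- run_example(cfg, R = 50, seed = 6, mode = "estimation")
  expect_identical(ex1, ex2)
  expect_equal(as.numeric(ex1$outputs),
               cases_averted(ex1$inputs, cfg))
  expect_true(all(as.numeric(ex1$outputs) <= cfg$I0))
  exd <- run_example(cfg, R = 50, seed = 6, mode = "decision")
  expect_equal(exd$outputs$policy + cfg$k, as.numeric(ex1$outputs))
  expect_equal(exd$outputs$status_quo, rep(0, 50))
})
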