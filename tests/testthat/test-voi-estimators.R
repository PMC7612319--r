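make_linear_problem <- function(R = 10000, seed = 21) {
  set.seed(seed)
  th <- parameter_draws(data.frame(t1 = rnorm(R), t2 = rnorm(R)))
  list(inputs = th, y = output_draws(th$t1 + th$t2))
}

test_that("estimation EVPPI matches the closed-form variance reduction", {
  pr <- make_linear_problem()
  e1 <- evppi(pr$y, pr$inputs, "t1")
  expect_voi(e1)
  expect_equal(e1$value, 1, tolerance = 0.06)
  # learning everything removes all variance
  eall <- evppi(pr$y, pr$inputs, c("t1", "t2"))
  expect_equal(eall$value, var(as.numeric(pr$y)), tolerance = 0.02)
  # learning an irrelevant parameter removes none
  set.seed(22)
  inp2 <- parameter_draws(cbind(as.data.frame(pr$inputs),
                                junk = rnorm(10000)))
  expect_lt(evppi(pr$y, inp2, "junk")$value, 0.02 * var(as.numeric(pr$y)))
})

test_that("estimators (a) and (b) agree via the law of total variance", {
  set.seed(23)
  R <- 5000
  th <- parameter_draws(data.frame(u = runif(R)))
  y <- output_draws(sin(2 * pi * th$u) + rnorm(R, 0, 0.4))
  e <- evppi(y, th, "u")
  expect_lt(abs(e$meta$estimator_a - e$meta$estimator_b) /
              var(as.numeric(y)), 0.02)
})

test_that("decision EVPPI is bounded by EVPI and finds closed-form values", {
  pr <- make_linear_problem(R = 20000, seed = 24)
  nb <- output_draws(data.frame(sq = rep(0, 20000),
                                pol = as.numeric(pr$y)))
  e_evpi <- evpi(nb)
  # full information recovers the EVPI
  e_full <- evppi(nb, pr$inputs, c("t1", "t2"))
  expect_equal(e_full$value, e_evpi$value, tolerance = 0.05)
  # one of two exchangeable parameters: E[max(0, t1)] = 1/sqrt(2*pi)
  e_half <- evppi(nb, pr$inputs, "t1")
  expect_lt(abs(e_half$value - 1 / sqrt(2 * pi)), 3 * 0.004 + 0.01)
  expect_lte(e_half$value, e_evpi$value + 1e-6)
  # irrelevant parameter has (almost) no decision value
  set.seed(25)
  inp2 <- parameter_draws(cbind(as.data.frame(pr$inputs),
                                junk = rnorm(20000)))
  expect_lt(evppi(nb, inp2, "junk")$value, 0.02 * e_evpi$value)
})

test_that("EVPPI validates its inputs", {
  pr <- make_linear_problem(R = 100)
  expect_error(evppi(pr$y, pr$inputs, "zzz"), "not in the draw table")
  expect_error(evppi(pr$y, pr$inputs, character(0)), "at least one")
  wide <- parameter_draws(as.data.frame(matrix(rnorm(100 * 16), 100)))
  expect_error(evppi(output_draws(rnorm(100)), wide, names(wide)),
               "more than 15")
})

test_that("EVSI follows the Beta-binomial closed form and is monotone in n", {
  set.seed(26)
  th <- parameter_draws(data.frame(p = rbeta(10000, 1, 1)))
  y <- output_draws(th$p)
  es <- evsi(y, th, binary_design("p"), n = c(0, 2, 10, 100, 10000),
             seed = 3)
  vals <- vapply(es, `[[`, numeric(1), "value")
  expect_equal(unname(vals[1]), 0)
  # closed form: EVSI = V0 * n / (a + b + n)
  expect_equal(unname(vals[2]), beta_binom_evsi(1, 1, 2), tolerance = 0.1)
  expect_equal(unname(vals[4]), beta_binom_evsi(1, 1, 100), tolerance = 0.1)
  # nondecreasing in n (within MC error)
  expect_true(all(diff(vals) > -0.002))
  # perfect-information limit: EVSI -> EVPPI of the informed parameter
  epp <- evppi(y, th, "p")
  expect_equal(unname(vals[5]), epp$value, tolerance = 0.05)
  expect_lte(max(vals), epp$value + 0.01 * epp$value + 1e-4)
})

test_that("decision EVSI approaches the informed parameter's EVPPI", {
  set.seed(27)
  R <- 8000
  th <- parameter_draws(data.frame(p = rbeta(R, 1, 1)))
  nb <- output_draws(data.frame(sq = rep(0, R), pol = th$p - 0.5))
  es <- evsi(nb, th, binary_design("p"), n = c(0, 10, 100, 5000), seed = 4)
  vals <- vapply(es, `[[`, numeric(1), "value")
  expect_equal(unname(vals[1]), 0)
  expect_true(all(diff(vals) > -0.003))
  epp <- evppi(nb, th, "p")
  expect_equal(unname(vals[4]), epp$value, tolerance = 0.1)
})

test_that("ENBS subtracts sampling costs and locates the optimum", {
  e10 <- voikit:::voi_estimate("EVSI", 10, meta = list(n = 50))
  expect_equal(enbs(e10, 4)$value, 6)
  expect_equal(enbs(e10, 10)$value, 0)
  grid <- list(voikit:::voi_estimate("EVSI", 2, meta = list(n = 10)),
               voikit:::voi_estimate("EVSI", 6, meta = list(n = 100)),
               voikit:::voi_estimate("EVSI", 7, meta = list(n = 1000)))
  df <- enbs(grid, cost = function(n) 0.004 * n)
  expect_equal(df$enbs, c(2 - 0.04, 6 - 0.4, 7 - 4))
  expect_equal(attr(df, "which_max"), 2L)
})

test_that("presentation transforms behave and clip as documented", {
  expect_equal(sd_remaining(100, 0), 10)
  expect_equal(sd_remaining(100, 100), 0)
  expect_equal(sd_remaining(100, 36), 8)
  expect_warning(s <- sd_remaining(100, 120), "clipping")
  expect_equal(s, 0)
  expect_equal(proportion_explained(4, 1), 0.25)
  expect_equal(proportion_explained(4, 0), 0)
  expect_equal(proportion_explained(4, 4), 1)
  expect_equal(proportion_explained(4, 5), 1)
})
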