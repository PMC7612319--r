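test_that("draw containers validate their invariants", {
  expect_error(parameter_draws(data.frame(a = 1)), "at least 2 rows")
  expect_error(parameter_draws(data.frame(a = 1:3, a = 4:6,
                                          check.names = FALSE)),
               "unique")
  expect_error(parameter_draws(data.frame(a = c(1, NA, 3))), "missing")
  expect_error(output_draws(data.frame(a = 1:5)), "at least 2 actions")
  expect_error(output_draws(c(1, NA)), "missing")
  th <- parameter_draws(data.frame(a = 1:5, b = 6:10))
  expect_equal(ndraws(th), 5)
  expect_equal(ndraws(output_draws(1:7)), 7)
  y <- output_draws(1:4)
  expect_error(voikit:::check_aligned(y, th), "4 draws.*5")
})

test_that("net benefit supports monetary, health and threshold forms", {
  eff <- data.frame(a1 = c(3, 3), a2 = c(0, 1))
  mon <- net_benefit(eff, decision_spec("monetary", wtp = 2,
                                        costs = c(a1 = 1, a2 = 0)))
  expect_equal(mon$a1, c(5, 5))
  hea <- net_benefit(eff, decision_spec("health", wtp = 2,
                                        costs = c(a1 = 1, a2 = 0)))
  expect_equal(hea$a1, c(2.5, 2.5))
  thr <- net_benefit(c(700, 300), decision_spec("threshold", threshold = 500))
  expect_equal(thr$policy, c(200, -200))
  expect_equal(thr$status_quo, c(0, 0))
  expect_error(net_benefit(eff, decision_spec("monetary", wtp = 2,
                                              costs = c(a1 = 1))),
               "no cost.*a2")
  expect_error(decision_spec("monetary", wtp = -1, costs = c(a1 = 0)),
               "positive")
  expect_error(decision_spec("threshold"), "threshold")
})

test_that("opportunity benefit enumerates per-draw decision changes", {
  nb <- output_draws(data.frame(a1 = rep(0, 4), a2 = c(-1, 3, -2, 4)))
  # current best is a2 (mean 1 > 0); opportunity arises where a1 wins
  expect_equal(opportunity_benefit(nb), c(1, 0, 2, 0))
  # dominance in every draw leaves nothing to gain
  dom <- output_draws(data.frame(a1 = c(1, 2, 3), a2 = c(2, 3, 4)))
  expect_equal(opportunity_benefit(dom), c(0, 0, 0))
  ident <- output_draws(data.frame(a1 = c(1, 2), a2 = c(1, 2)))
  expect_warning(ob <- opportunity_benefit(ident), "tie")
  expect_equal(ob, c(0, 0))
  expect_error(opportunity_benefit(output_draws(1:5)), "decision")
})

test_that("decision EVPI equals both the opportunity-benefit mean and the
           two-term formula, and is never negative", {
  nb <- output_draws(data.frame(a1 = rep(0, 4), a2 = c(-1, 3, -2, 4)))
  expect_equal(evpi(nb)$value, 0.75)
  set.seed(41)
  for (rep in 1:5) {
    m <- matrix(rnorm(60 * 3), 60, 3)
    nbr <- output_draws(as.data.frame(m))
    two_term <- mean(apply(m, 1, max)) - max(colMeans(m))
    e <- evpi(nbr)
    expect_equal(e$value, two_term, tolerance = 1e-12)
    expect_gte(e$value, 0)
  }
  # a certain decision has no value of information
  shift <- output_draws(data.frame(a1 = rnorm(50), a2 = rnorm(50)))
  certain <- output_draws(data.frame(a1 = shift$a1, a2 = shift$a1 + 3))
  expect_equal(evpi(certain)$value, 0)
})

test_that("estimation EVPI is the empirical variance (divisor R - 1)", {
  expect_equal(evpi(output_draws(c(1, 2, 3, 4)))$value, 5 / 3)
  expect_equal(evpi(output_draws(rep(2, 10)))$value, 0)
  set.seed(5)
  y <- rnorm(200, 3, 2)
  expect_equal(evpi(output_draws(y))$value,
               sum((y - mean(y))^2) / 199, tolerance = 1e-12)
  expect_equal(evpi(output_draws(3 * y))$value, 9 * evpi(output_draws(y))$value)
})

test_that("decision EVPI converges to E[max(0, Z)] for a standard normal
           incremental net benefit", {
  set.seed(7)
  theta <- rnorm(2e4)
  nb <- output_draws(data.frame(status_quo = rep(0, 2e4), policy = theta))
  e <- evpi(nb)
  expect_lt(abs(e$value - 1 / sqrt(2 * pi)), 3 * e$mc_se)
})
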