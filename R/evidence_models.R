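#' Probabilistic bias model for an indirect proportion estimate
#'
#' When published evidence on a proportion comes from a different context
#' (area, period, population), the context-specific "debiased" parameter
#' is modelled as \eqn{\pi_0 = expit(logit(\pi_a) + \delta)} with a random
#' bias \eqn{\delta \sim N(shift, \sigma^2)} on the logit scale: the logit
#' transform keeps \eqn{\pi_0} in (0, 1) for any bias magnitude.
#'
#' @param sigma_bias Standard deviation of the bias on the logit scale
#'   (>= 0).
#' @param shift Mean of the bias (0 for symmetric uncertainty about the
#'   direction; negative if the target context is believed smaller).
#' @return A list of class `"bias_model"`.
#' @export
bias_model <- function(sigma_bias, shift = 0) {
  stopifnot(sigma_bias >= 0, is.finite(shift))
  structure(list(sigma_bias = sigma_bias, shift = shift),
            class = "bias_model")
}

#' Apply a probabilistic bias model to draws of a proportion
#'
#' For each draw of the (possibly biased) published parameter \eqn{\pi_a},
#' samples a bias \eqn{\delta^{(r)}} and returns the debiased draw
#' \eqn{\pi_0^{(r)} = expit(logit(\pi_a^{(r)}) + \delta^{(r)})}.
#'
#' @param pi_a_draws Vector of draws in (0, 1).
#' @param bias A [bias_model()].
#' @param seed Integer seed.
#' @return Vector of debiased draws in (0, 1).
#' @examples
#' expit <- function(x) 1 / (1 + exp(-x))
#' debias(rep(0.5, 3), bias_model(0, shift = log(1.5)))  # all 0.6
#' @export
debias <- function(pi_a_draws, bias, seed = 1) {
  stopifnot(inherits(bias, "bias_model"))
  if (any(pi_a_draws <= 0 | pi_a_draws >= 1))
    stop("draws must lie strictly in (0, 1)")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  delta <- stats::rnorm(length(pi_a_draws), bias$shift, bias$sigma_bias)
  expit(logit(pi_a_draws) + delta)
}

#' Solve for the bias SD matching an elicited quantile of the bias ratio
#'
#' Elicitation is easier on the ratio scale: "we are 90% sure the target
#' value is no more than 20% larger than the published estimate" means the
#' 0.9 quantile of \eqn{\pi_0 / \pi_a} should equal 1.2.  This function
#' finds, by bisection, the logit-scale bias SD \eqn{\sigma} under which
#' the Monte Carlo distribution of the ratio has that quantile, using a
#' fixed common-random-numbers sample so the objective is smooth in
#' \eqn{\sigma}.
#'
#' @param pi_a_dist Either a vector of draws of \eqn{\pi_a} in (0, 1), or a
#'   function `function(n)` generating such draws (e.g.
#'   `function(n) rbeta(n, 5.7, 8.9)`).
#' @param ratio_target Target ratio, > 1.
#' @param prob Quantile level, in (0.5, 1); default 0.9.
#' @param seed Integer seed for the common-random-numbers sample.
#' @param n_draws Size of that sample (default 1e5).
#' @param tol Bisection tolerance on \eqn{\sigma} (default 1e-4).
#' @return The bias SD \eqn{\sigma}.
#' @export
solve_bias_sd <- function(pi_a_dist, ratio_target, prob = 0.9, seed = 1,
                          n_draws = 1e5, tol = 1e-4) {
  if (ratio_target <= 1)
    stop("'ratio_target' must exceed 1 (no bias SD can lower the upper ",
         "quantile of the ratio below 1)")
  if (prob <= 0.5 || prob >= 1) stop("'prob' must lie in (0.5, 1)")
  old <- local_seed(seed)
  pi_a <- if (is.function(pi_a_dist)) pi_a_dist(n_draws) else
    sample(pi_a_dist, n_draws, replace = TRUE)
  z <- stats::rnorm(n_draws)
  restore_seed(old)
  if (any(pi_a <= 0 | pi_a >= 1)) stop("pi_a draws must lie in (0, 1)")
  lp <- logit(pi_a)
  # nearest-rank empirical quantile of the ratio at bias SD s
  rank <- pmax(1L, as.integer(ceiling(prob * n_draws)))
  qratio <- function(s) {
    ratio <- expit(lp + s * z) / pi_a
    sort(ratio, partial = rank)[rank]
  }
  lo <- 0; hi <- 0.5
  while (qratio(hi) < ratio_target) {
    hi <- hi * 2
    if (hi > 50) stop("could not bracket the target ratio; is it attainable?")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (qratio(mid) < ratio_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Evidence on a proportion from multiple exchangeable areas
#'
#' Published estimates \eqn{x_i} of the same proportion in M areas, with
#' uncertainty \eqn{s_i} expressed as the SD of \eqn{logit(x_i)}.  If
#' 95% interval limits are given instead, `s` is derived as
#' \eqn{(logit(upper) - logit(lower)) / (2 \times 1.96)}.
#'
#' @param estimate Vector of proportion estimates in (0, 1).
#' @param s Vector of logit-scale SDs (> 0), or `NULL` to derive from
#'   `lower`/`upper`.
#' @param lower,upper Optional 95% interval limits in (0, 1).
#' @param area Optional area labels.
#' @return A data frame of class `"hierarchical_evidence"` with columns
#'   `area`, `estimate`, `s`.
#' @export
hierarchical_evidence <- function(estimate, s = NULL, lower = NULL,
                                  upper = NULL, area = NULL) {
  if (any(estimate <= 0 | estimate >= 1))
    stop("estimates must lie strictly in (0, 1)")
  if (is.null(s)) {
    if (is.null(lower) || is.null(upper))
      stop("supply either 's' or both 'lower' and 'upper'")
    if (any(lower <= 0 | upper >= 1 | lower >= upper))
      stop("interval limits must satisfy 0 < lower < upper < 1")
    s <- (logit(upper) - logit(lower)) / (2 * stats::qnorm(0.975))
  }
  if (any(s <= 0)) stop("logit-scale SDs must be positive")
  if (is.null(area)) area <- paste0("area", seq_along(estimate))
  structure(data.frame(area = area, estimate = estimate, s = s),
            class = c("hierarchical_evidence", "data.frame"))
}

#' Posterior draws of a target-area proportion from hierarchical evidence
#'
#' Fits the Bayesian hierarchical model
#' \deqn{logit(x_i) \sim N(logit(\pi_i), s_i^2), \quad
#'       logit(\pi_i) \sim N(\mu^{(m)}, \sigma^{(m)2})}
#' with hyperpriors \eqn{\mu^{(m)} \sim N(0, 10^2)} and \eqn{\sigma^{(m)}
#' \sim} half-Normal(0, 1), by MCMC (JAGS, 4 chains, half warm-up), and
#' returns draws from the posterior predictive distribution of the
#' proportion \eqn{\pi_0} in a new exchangeable area:
#' \eqn{logit(\pi_0) \sim N(\mu^{(m)}, \sigma^{(m)2})} integrated over the
#' hyperparameter posterior.  Errors if any monitored quantity has
#' R-hat > 1.05.
#'
#' @param evidence A [hierarchical_evidence()].
#' @param R Number of posterior draws to return.
#' @param seed Integer seed.
#' @param prior_mu_sd SD of the normal hyperprior on \eqn{\mu^{(m)}}
#'   (logit scale; default 10).
#' @param prior_sigma_sd Scale of the half-normal hyperprior on
#'   \eqn{\sigma^{(m)}} (default 1).
#' @param n_adapt,n_burnin Adaptation and burn-in iterations per chain.
#' @param n_iter Sampling iterations per chain (the returned R draws are
#'   an even subsample of the pooled chains).
#' @return Vector of R draws of \eqn{\pi_0} in (0, 1), with attribute
#'   `diagnostics` (R-hat values and hyperparameter posterior summaries).
#' @export
hierarchical_target <- function(evidence, R = 4000, seed = 1,
                                prior_mu_sd = 10, prior_sigma_sd = 1,
                                n_adapt = 1000, n_burnin = 2000,
                                n_iter = NULL) {
  stopifnot(inherits(evidence, "hierarchical_evidence"), R >= 2)
  if (!requireNamespace("rjags", quietly = TRUE) ||
      !requireNamespace("coda", quietly = TRUE))
    stop("hierarchical_target requires the 'rjags' and 'coda' packages")
  model_str <- "
    model {
      for (i in 1:M) {
        lx[i] ~ dnorm(lpi[i], 1 / (s[i] * s[i]))
        lpi[i] ~ dnorm(mu, prec)
      }
      mu ~ dnorm(0, 1 / (prior_mu_sd * prior_mu_sd))
      sigma ~ dnorm(0, 1 / (prior_sigma_sd * prior_sigma_sd)) T(0,)
      prec <- 1 / (sigma * sigma)
      lpi0 ~ dnorm(mu, prec)
      pi0 <- 1 / (1 + exp(-lpi0))
    }"
  dat <- list(M = nrow(evidence), lx = logit(evidence$estimate),
              s = evidence$s, prior_mu_sd = prior_mu_sd,
              prior_sigma_sd = prior_sigma_sd)
  n_chains <- 4
  inits <- lapply(seq_len(n_chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + i) %% .Machine$integer.max))
  if (is.null(n_iter)) n_iter <- max(4000, ceiling(R / n_chains))
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  stats::update(jm, n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("pi0", "mu", "sigma"), n.iter = n_iter,
                              progress.bar = "none")
  gd <- coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)
  rhat <- gd$psrf[, 1]
  if (any(rhat > 1.05, na.rm = TRUE))
    stop("MCMC did not converge: R-hat = ",
         paste(sprintf("%s %.3f", rownames(gd$psrf), rhat), collapse = ", "))
  all <- do.call(rbind, lapply(samp, as.matrix))
  pi0 <- all[, "pi0"]
  if (length(pi0) > R)
    pi0 <- pi0[round(seq(1, length(pi0), length.out = R))]
  attr(pi0, "diagnostics") <- list(
    rhat = rhat,
    mu_mean = mean(all[, "mu"]), mu_sd = stats::sd(all[, "mu"]),
    sigma_mean = mean(all[, "sigma"]), sigma_sd = stats::sd(all[, "sigma"]))
  pi0
}

#' Synthetic multi-area evidence fixture
#'
#' Generates a small table of area-level proportion estimates around a
#' common centre, with selectable between-area spread, emulating published
#' estimates of the transport PM2.5 share from several comparable areas.
#' Entirely synthetic: the multi-area dataset this stands in for is not
#' published.
#'
#' @param M Number of areas (default 6).
#' @param spread `"high"` or `"low"` between-area heterogeneity
#'   (between-area SD 0.8 or 0.15 on the logit scale).
#' @param centre Central proportion (default 0.4).
#' @param s Logit-scale SD of each published estimate (default 0.15).
#' @param seed Integer seed.
#' @return A [hierarchical_evidence()].
#' @export
synthetic_areas <- function(M = 6, spread = c("high", "low"), centre = 0.4,
                            s = 0.15, seed = 1) {
  spread <- match.arg(spread)
  tau <- if (spread == "high") 0.8 else 0.15
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lpi <- stats::rnorm(M, logit(centre), tau)
  x <- expit(stats::rnorm(M, lpi, s))
  hierarchical_evidence(estimate = x, s = rep_len(s, M))
}
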