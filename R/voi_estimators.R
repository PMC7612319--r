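#' Expected value of partial perfect information
#'
#' Estimates the expected gain from learning a subset of parameters
#' exactly, by nonparametric regression of the sampled outputs on the
#' sampled values of those parameters ([fit_flexible_mean()]).
#'
#' For an estimation problem, EVPPI is the expected reduction in variance
#' of the output, \eqn{var(Y) - E_\phi[var_{Y|\phi}(Y)]}, estimated (by the
#' law of total variance) as the empirical variance of the fitted values
#' (estimator "a").  The companion estimator "b", \eqn{var(y) -
#' \sigma^2} with \eqn{\sigma^2} the residual variance, is reported in
#' `meta` together with their discrepancy.
#'
#' For a decision problem, one surface is fitted per action, and
#' \deqn{EVPPI = \frac{1}{R}\sum_r \max_a \hat{NB}_a^{(r)} -
#'   \max_a \frac{1}{R}\sum_r NB_a^{(r)},}
#' mimicking the decision we would take knowing \eqn{\phi} (maximizing
#' fitted net benefit) against the decision under current information.
#'
#' The default backend is `spline_gam` for up to 4 parameters and
#' `adaptive_splines` for 5 to 15; joint EVPPI for more than 15 parameters
#' is refused (reliable nonparametric regression in that dimension is an
#' open problem).
#'
#' @param outputs An [output_draws()] of either kind.
#' @param inputs A [parameter_draws()] table aligned with `outputs`.
#' @param pars Character vector naming the parameter subset \eqn{\phi}.
#' @param method Regression backend (see [fit_flexible_mean()]); `NULL`
#'   picks the default by the size of `pars`.
#' @param options Backend options passed to [fit_flexible_mean()].
#' @param nboot If > 0, number of bootstrap resamples (over draws, refitting
#'   the regression) used for the Monte Carlo standard error.  Default 0:
#'   a cheap plug-in standard error is reported instead, which accounts for
#'   sampling of the draws but not for smoothing uncertainty.
#' @return A `voi_estimate`.
#' @examples
#' th <- parameter_draws(data.frame(a = rnorm(2000), b = rnorm(2000)))
#' y  <- output_draws(th$a + th$b)
#' evppi(y, th, "a")$value   # close to var(a) = 1
#' @export
evppi <- function(outputs, inputs, pars, method = NULL, options = list(),
                  nboot = 0) {
  inputs <- as.data.frame(inputs)
  check_aligned(outputs, parameter_draws(inputs))
  if (!length(pars)) stop("'pars' must name at least one parameter")
  missing <- setdiff(pars, names(inputs))
  if (length(missing))
    stop("parameter(s) not in the draw table: ", paste(missing, collapse = ", "))
  method <- default_method(method, length(pars))
  x <- inputs[pars]
  est <- regression_voi(outputs, x, method, options)
  est <- voi_estimate("EVPPI", est$value, est$mc_se,
                      meta = c(list(pars = pars, method = method), est$meta))
  if (nboot > 0)
    est$mc_se <- bootstrap_se(outputs, x, method, options, nboot)
  est
}

#' Expected value of sample information
#'
#' Estimates the expected gain from a proposed study of sample size n,
#' before its data Z are observed.  For each parameter draw
#' \eqn{\theta^{(r)}}, a study result is simulated from the sampling model
#' \eqn{Z^{(r)} \sim p(Z | \theta^{(r)})} and reduced to the design's
#' summary statistic \eqn{T(Z^{(r)})}; the sampled outputs are then
#' regressed on \eqn{T(Z^{(r)})} exactly as in [evppi()].  For an
#' estimation problem the value is the expected reduction in output
#' variance after the study; for a decision problem it is the expected
#' gain in net benefit from deciding after seeing the data.
#'
#' @param outputs,inputs As in [evppi()].
#' @param design A [study_design()], e.g. [binary_design()].
#' @param n Vector of study sample sizes to compare.  `n = 0` gives 0.
#' @param seed Integer seed governing the predictive-data simulation (one
#'   derived stream per element of `n`).
#' @param method,options,nboot As in [evppi()]; the default backend is
#'   chosen by the dimension of the summary statistic.
#' @return A list of `voi_estimate`s, one per element of `n` (named by n).
#' @examples
#' th <- parameter_draws(data.frame(p = rbeta(5000, 1, 1)))
#' y  <- output_draws(th$p)
#' evsi(y, th, binary_design("p"), n = 2, seed = 1)[[1]]$value  # ~ 1/24
#' @export
evsi <- function(outputs, inputs, design, n, seed = 1,
                 method = NULL, options = list(), nboot = 0) {
  stopifnot(inherits(design, "study_design"))
  inputs <- as.data.frame(inputs)
  check_aligned(outputs, parameter_draws(inputs))
  if (any(n < 0) || any(n != floor(n)))
    stop("study sizes 'n' must be nonnegative integers")
  out <- vector("list", length(n))
  names(out) <- as.character(n)
  for (i in seq_along(n)) {
    ni <- n[i]
    if (ni == 0) {
      out[[i]] <- voi_estimate("EVSI", 0, 0,
        meta = list(design = design$name, n = 0, method = NA_character_))
      next
    }
    old <- local_seed((seed + i - 1L) %% .Machine$integer.max)
    Tz <- design$simulate(inputs, ni)
    restore_seed(old)
    Tz <- as.data.frame(Tz)
    names(Tz) <- paste0("T", seq_len(ncol(Tz)))
    mth <- default_method(method, ncol(Tz))
    est <- regression_voi(outputs, Tz, mth, options)
    e <- voi_estimate("EVSI", est$value, est$mc_se,
           meta = c(list(design = design$name, n = ni, method = mth),
                    est$meta))
    if (nboot > 0)
      e$mc_se <- bootstrap_se(outputs, Tz, mth, options, nboot)
    out[[i]] <- e
  }
  out
}

#' Expected net benefit of sampling
#'
#' ENBS trades the expected benefit of a study against its cost:
#' \eqn{ENBS_Z = EVSI_Z - C_Z}.  The cost must be in the same units as the
#' net benefit (for decision problems) or the monetized variance reduction
#' (for estimation problems); it may be negative.
#'
#' @param evsi A single `voi_estimate`, or a list of them as returned by
#'   [evsi()] over a grid of sample sizes.
#' @param cost Sampling cost: a scalar, a vector matching the grid, or a
#'   function of n.
#' @return For a single estimate, a `voi_estimate` of measure `"ENBS"`.
#'   For a grid, a data frame with columns `n`, `evsi`, `cost`, `enbs` and
#'   attribute `which_max` (the row index of the best design).
#' @export
enbs <- function(evsi, cost) {
  if (inherits(evsi, "voi_estimate")) {
    cz <- if (is.function(cost)) cost(evsi$meta$n) else cost
    return(voi_estimate("ENBS", evsi$value - cz, evsi$mc_se,
                        meta = list(evsi = evsi$value, cost = cz,
                                    n = evsi$meta$n)))
  }
  stopifnot(is.list(evsi), all(vapply(evsi, inherits, logical(1), "voi_estimate")))
  ns <- vapply(evsi, function(e) e$meta$n, numeric(1))
  vals <- vapply(evsi, `[[`, numeric(1), "value")
  cz <- if (is.function(cost)) vapply(ns, cost, numeric(1)) else rep_len(cost, length(ns))
  df <- data.frame(n = ns, evsi = vals, cost = cz, enbs = vals - cz)
  attr(df, "which_max") <- which.max(df$enbs)
  df
}

#' Standard deviation of the output remaining after learning a parameter
#'
#' Computes \eqn{\sqrt{var(Y) - EVPPI_\phi}}, an estimate of the standard
#' deviation of the output that would remain if \eqn{\phi} were learnt
#' exactly.  Note this is an estimate of the remaining SD derived from the
#' expected remaining variance; it is not quite the same as the
#' expectation of the remaining SD.
#'
#' @param var_y Variance of the output under current information.
#' @param evppi_value EVPPI of the parameter(s), same units.
#' @return Scalar SD; values of `evppi_value` above `var_y` (possible from
#'   Monte Carlo noise) are clipped with a warning.
#' @export
sd_remaining <- function(var_y, evppi_value) {
  if (inherits(evppi_value, "voi_estimate")) evppi_value <- evppi_value$value
  stopifnot(var_y >= 0, evppi_value >= 0)
  if (evppi_value > var_y) {
    warning("EVPPI exceeds var(Y) (Monte Carlo noise); clipping to var(Y)")
    evppi_value <- var_y
  }
  sqrt(var_y - evppi_value)
}

#' Proportion of output variance removable by learning a parameter
#'
#' \eqn{EVPPI_\phi / var(Y)}, clipped to \[0, 1\]: the fraction of current
#' output uncertainty attributable to \eqn{\phi} (the main-effect
#' sensitivity index).
#'
#' @inheritParams sd_remaining
#' @return Scalar in \[0, 1\].
#' @export
proportion_explained <- function(var_y, evppi_value) {
  if (inherits(evppi_value, "voi_estimate")) evppi_value <- evppi_value$value
  stopifnot(var_y > 0, evppi_value >= 0)
  min(1, max(0, evppi_value / var_y))
}

## ---- shared machinery ----

default_method <- function(method, p) {
  if (!is.null(method)) return(match.arg(method,
    c("spline_gam", "adaptive_splines", "gaussian_process", "auto")))
  if (p <= 4) "spline_gam"
  else if (p <= 15) "adaptive_splines"
  else stop("joint EVPPI/EVSI for more than 15 parameters is not ",
            "supported: no regression method is reliable in that dimension")
}

# core regression-based estimator, shared by evppi and evsi
regression_voi <- function(outputs, x, method, options) {
  kind <- output_kind(outputs)
  if (kind == "estimation") {
    y <- as.numeric(outputs)
    fit <- fit_flexible_mean(x, y, method, options)
    a <- stats::var(fit$fitted)
    b <- stats::var(y) - fit$resid_var
    value <- min(a, stats::var(y))  # EVPPI cannot exceed total variance
    list(value = value, mc_se = var_se(fit$fitted),
         meta = list(estimator_a = a, estimator_b = b,
                     discrepancy = a - b, var_y = stats::var(y),
                     diagnostics = fit$diagnostics))
  } else {
    nb <- as.data.frame(outputs)
    fitted <- matrix(NA_real_, nrow(nb), ncol(nb))
    diags <- vector("list", ncol(nb))
    for (a in seq_len(ncol(nb))) {
      ya <- nb[[a]]
      if (stats::sd(ya) == 0) {          # e.g. the status-quo action
        fitted[, a] <- mean(ya)
      } else {
        f <- fit_flexible_mean(x, ya, method, options)
        fitted[, a] <- f$fitted
        diags[[a]] <- f$diagnostics
      }
    }
    perfect <- apply(fitted, 1, max)
    value <- mean(perfect) - max(colMeans(as.matrix(nb)))
    list(value = value, mc_se = stats::sd(perfect) / sqrt(length(perfect)),
         meta = list(diagnostics = diags))
  }
}

bootstrap_se <- function(outputs, x, method, options, nboot) {
  kind <- output_kind(outputs)
  R <- ndraws(outputs)
  vals <- vapply(seq_len(nboot), function(b) {
    idx <- sample.int(R, R, replace = TRUE)
    ob <- if (kind == "estimation") output_draws(as.numeric(outputs)[idx])
          else output_draws(as.data.frame(outputs)[idx, , drop = FALSE], "decision")
    regression_voi(ob, x[idx, , drop = FALSE], method, options)$value
  }, numeric(1))
  stats::sd(vals)
}
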