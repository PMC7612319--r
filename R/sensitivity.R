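#' Specify how one parameter is varied in a tornado analysis
#'
#' @param qfun Quantile function of the parameter's uncertainty
#'   distribution (e.g. `function(p) qbeta(p, 5.7, 8.9)`), used for the
#'   credible limits and the median.  If `NULL`, empirical quantiles of the
#'   supplied draws are used (probabilistic tornado only, unless `draws`
#'   given).
#' @param draws Optional vector of draws to take empirical quantiles from.
#' @return A list of class `"tornado_param"`.
#' @export
tornado_param <- function(qfun = NULL, draws = NULL) {
  if (is.null(qfun) && is.null(draws))
    qfun <- NULL  # empirical quantiles of the analysis draws
  structure(list(qfun = qfun, draws = draws), class = "tornado_param")
}

#' Specify a jointly-varied parameter group in a tornado analysis
#'
#' Correlated parameters (such as the four dose-response curve parameters)
#' should not be varied one at a time: the group is conditioned jointly on
#' two "extreme" parameter sets, typically whole curves selected by
#' [strength_extremes()].
#'
#' @param members Names of the grouped parameters.
#' @param low,high Named vectors: the parameter sets for the weak and
#'   strong extremes.
#' @param central Optional named vector of central values (required for
#'   [tornado_fixed()]; e.g. component-wise medians of the joint sample).
#' @return A list of class `"tornado_group"`.
#' @export
tornado_group <- function(members, low, high, central = NULL) {
  stopifnot(all(members %in% names(low)), all(members %in% names(high)))
  structure(list(members = members, low = low[members],
                 high = high[members],
                 central = if (!is.null(central)) central[members]),
            class = "tornado_group")
}

q_of <- function(spec, p, analysis_draws = NULL) {
  if (!is.null(spec$qfun)) return(spec$qfun(p))
  dr <- if (!is.null(spec$draws)) spec$draws else analysis_draws
  if (is.null(dr)) stop("no quantile function or draws for a tornado parameter")
  as.numeric(stats::quantile(dr, p, type = 1))
}

#' Non-probabilistic (fixed) tornado analysis
#'
#' Classical one-way sensitivity analysis: each parameter in turn is set to
#' its lower and upper credible limits while all other parameters are held
#' at their medians, and the model output is recorded.  Parameter groups
#' are conditioned jointly on their two extreme sets.  The base case is the
#' model evaluated with every parameter at its median — note that for a
#' nonlinear model this \eqn{f(E(\theta))}-style point estimate is a biased
#' estimate of the expected output \eqn{E(f(\theta))} (compare
#' [tornado_probabilistic()]).
#'
#' @param model Function mapping a data frame of parameter values (one row
#'   per evaluation) to a numeric output vector.
#' @param params Named list of [tornado_param()] / [tornado_group()] specs;
#'   scalar entries need a quantile function or draws, groups need
#'   `central`.
#' @param probs Credible-limit probabilities (default 2.5% and 97.5%).
#' @return Data frame with one row per (group of) parameter(s): columns
#'   `parameter`, `low_value`, `high_value` (NA for groups), `out_low`,
#'   `out_high`, `range`; ordered by decreasing `range`; attribute `base`
#'   holds the all-medians output.
#' @export
tornado_fixed <- function(model, params, probs = c(0.025, 0.975)) {
  stopifnot(is.function(model), length(probs) == 2, probs[1] < probs[2])
  centre <- tornado_centre(params)
  base <- model(centre)[1]
  rows <- lapply(names(params), function(nm) {
    sp <- params[[nm]]
    if (inherits(sp, "tornado_group")) {
      lo_df <- centre; lo_df[sp$members] <- as.list(sp$low)
      hi_df <- centre; hi_df[sp$members] <- as.list(sp$high)
      data.frame(parameter = nm, low_value = NA_real_, high_value = NA_real_,
                 out_low = model(lo_df)[1], out_high = model(hi_df)[1])
    } else {
      lims <- c(q_of(sp, probs[1]), q_of(sp, probs[2]))
      if (lims[1] >= lims[2]) stop("degenerate credible limits for ", nm)
      outs <- vapply(lims, function(v) {
        df <- centre; df[[nm]] <- v; model(df)[1]
      }, numeric(1))
      data.frame(parameter = nm, low_value = lims[1], high_value = lims[2],
                 out_low = outs[1], out_high = outs[2])
    }
  })
  finish_tornado(do.call(rbind, rows), base)
}

tornado_centre <- function(params) {
  vals <- list()
  for (nm in names(params)) {
    sp <- params[[nm]]
    if (inherits(sp, "tornado_group")) {
      if (is.null(sp$central))
        stop("group '", nm, "' needs 'central' values for a fixed tornado")
      vals[sp$members] <- as.list(sp$central)
    } else {
      vals[[nm]] <- q_of(sp, 0.5)
    }
  }
  as.data.frame(vals)
}

#' Probabilistic tornado analysis
#'
#' One-way sensitivity analysis that accounts for the uncertainty in the
#' parameters not being varied: for each parameter, the output reported at
#' each credible limit is the Monte Carlo mean of the model with that
#' parameter clamped to the limit and all other parameters still sampled
#' from their distributions, \eqn{E(f(\theta) | \mu = \mu_L)} etc.  This is
#' valid when the varied parameter is independent of the rest, which is
#' checked empirically; correlated parameters must be varied jointly as a
#' [tornado_group()] (conditioned on two extreme parameter sets, e.g. from
#' [strength_extremes()]).  The base case is the Monte Carlo mean with a
#' 95% interval.
#'
#' @inheritParams tornado_fixed
#' @param draws A [parameter_draws()] sample of all model parameters.
#' @param cor_threshold Refuse to clamp a scalar parameter whose absolute
#'   empirical correlation with any parameter outside its own group
#'   exceeds this (default 0.1).
#' @return As [tornado_fixed()]; attributes `base` (Monte Carlo mean) and
#'   `base_interval` (2.5%/97.5% quantiles of the sampled outputs).
#' @export
tornado_probabilistic <- function(model, draws, params,
                                  probs = c(0.025, 0.975),
                                  cor_threshold = 0.1) {
  stopifnot(is.function(model), length(probs) == 2, probs[1] < probs[2])
  draws <- as.data.frame(draws)
  y0 <- model(draws)
  base <- mean(y0)
  grouped <- unlist(lapply(params, function(sp)
    if (inherits(sp, "tornado_group")) sp$members else NULL))
  rows <- lapply(names(params), function(nm) {
    sp <- params[[nm]]
    if (inherits(sp, "tornado_group")) {
      out <- vapply(list(sp$low, sp$high), function(dset) {
        df <- draws
        df[sp$members] <- lapply(sp$members, function(m)
          rep(dset[[m]], nrow(df)))
        mean(model(df))
      }, numeric(1))
      data.frame(parameter = nm, low_value = NA_real_, high_value = NA_real_,
                 out_low = out[1], out_high = out[2])
    } else {
      others <- setdiff(setdiff(names(draws), nm), grouped)
      if (length(others)) {
        cors <- abs(stats::cor(draws[[nm]], draws[others]))
        if (any(cors > cor_threshold))
          stop("parameter '", nm, "' is correlated with ",
               paste(others[cors > cor_threshold], collapse = ", "),
               " (|r| > ", cor_threshold, "); clamping it alone would ",
               "misrepresent the joint uncertainty - vary these jointly ",
               "as a tornado_group")
      }
      lims <- c(q_of(sp, probs[1], draws[[nm]]),
                q_of(sp, probs[2], draws[[nm]]))
      if (lims[1] >= lims[2]) stop("degenerate credible limits for ", nm)
      outs <- vapply(lims, function(v) {
        df <- draws; df[[nm]] <- v; mean(model(df))
      }, numeric(1))
      data.frame(parameter = nm, low_value = lims[1], high_value = lims[2],
                 out_low = outs[1], out_high = outs[2])
    }
  })
  res <- finish_tornado(do.call(rbind, rows), base)
  attr(res, "base_interval") <- as.numeric(stats::quantile(y0, probs))
  res
}

finish_tornado <- function(df, base) {
  df$range <- abs(df$out_high - df$out_low)
  df <- df[order(-df$range), ]
  rownames(df) <- NULL
  attr(df, "base") <- base
  df
}

#' Tornado specification for the example health impact model
#'
#' Builds the parameter list used by the tornado functions for the fixture:
#' closed-form credible limits for the background concentration (log-normal
#' quantiles) and the transport share (Beta quantiles), and a joint
#' dose-response group conditioned on the weak/strong extreme curves from
#' [strength_extremes()] (central values: component-wise medians of the
#' joint sample).
#'
#' @param config A [health_model_config()].
#' @param d_draws Data frame of sampled dose-response parameters.
#' @param ... Passed to [strength_extremes()].
#' @return Named list of tornado specs (`mu`, `pi`, `dose_response`).
#' @export
example_tornado_params <- function(config, d_draws, ...) {
  ext <- strength_extremes(d_draws, ...)
  central <- vapply(as.data.frame(d_draws)[c("alpha", "beta", "gamma", "tau")],
                    stats::median, numeric(1))
  list(
    pi = tornado_param(function(p) stats::qbeta(p, config$pi_shape1,
                                                config$pi_shape2)),
    mu = tornado_param(function(p) stats::qlnorm(p, config$mu_meanlog,
                                                 config$mu_sdlog)),
    dose_response = tornado_group(c("alpha", "beta", "gamma", "tau"),
                                  low = ext$lower, high = ext$upper,
                                  central = central))
}
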