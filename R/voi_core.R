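#' Specify how per-action benefits map to net benefit
#'
#' A decision problem compares actions by net benefit
#' \eqn{NB_a(\theta) = \lambda Y_a(\theta) - C_a}, where \eqn{\lambda} is the
#' willingness to pay per unit of health benefit and \eqn{C_a} the cost of
#' action a.  Three parameterizations are supported:
#' `"monetary"` (\eqn{\lambda Y - C}), `"health"` (\eqn{Y - C/\lambda},
#' i.e. net benefit on the health scale), and `"threshold"` — the policy
#' form used in the worked health impact model, where a single policy is
#' adopted if its expected benefit exceeds a practical-significance
#' threshold k, so \eqn{NB_2 = Y - k} and \eqn{NB_1 \equiv 0}.
#'
#' @param form `"monetary"`, `"health"` or `"threshold"`.
#' @param wtp Willingness to pay \eqn{\lambda > 0} (required for the
#'   monetary and health forms).
#' @param costs Named vector of per-action costs \eqn{C_a} (monetary and
#'   health forms); missing actions are an error in [net_benefit()].
#' @param threshold Decision threshold k, in output units (threshold form).
#' @return A list of class `"decision_spec"`.
#' @export
decision_spec <- function(form = c("monetary", "health", "threshold"),
                          wtp = NULL, costs = NULL, threshold = NULL) {
  form <- match.arg(form)
  if (form == "threshold") {
    if (is.null(threshold) || !is.finite(threshold))
      stop("threshold form requires a finite 'threshold'")
    if (!is.null(wtp) || !is.null(costs))
      stop("threshold form takes only 'threshold', not wtp/costs")
  } else {
    if (is.null(wtp) || wtp <= 0)
      stop("willingness-to-pay 'wtp' must be a positive number")
    if (is.null(costs)) stop("per-action 'costs' are required")
  }
  structure(list(form = form, wtp = wtp, costs = costs,
                 threshold = threshold), class = "decision_spec")
}

#' Build net benefit draws from per-action benefit draws
#'
#' @param effects For the monetary/health forms, a data frame of per-action
#'   benefit draws \eqn{Y_a(\theta^{(r)})} (one column per action).  For the
#'   threshold form, a single vector or one-column data frame of model
#'   output draws \eqn{f(\theta^{(r)})}.
#' @param spec A [decision_spec()].
#' @return An [output_draws()] of kind `"decision"`.  Threshold form returns
#'   actions `status_quo` (identically 0) and `policy` (\eqn{f(\theta)-k}).
#' @examples
#' net_benefit(data.frame(a1 = 3, a2 = c(1, 5)),
#'             decision_spec("monetary", wtp = 2, costs = c(a1 = 1, a2 = 0)))
#' @export
net_benefit <- function(effects, spec) {
  stopifnot(inherits(spec, "decision_spec"))
  if (spec$form == "threshold") {
    y <- if (is.data.frame(effects) || is.matrix(effects)) {
      if (ncol(effects) != 1)
        stop("threshold form expects a single output column")
      as.numeric(effects[[1]])
    } else as.numeric(effects)
    nb <- data.frame(status_quo = rep(0, length(y)),
                     policy = y - spec$threshold)
    return(output_draws(nb, "decision"))
  }
  effects <- as.data.frame(effects)
  if (ncol(effects) < 1) stop("need at least one action")
  miss <- setdiff(names(effects), names(spec$costs))
  if (length(miss))
    stop("no cost specified for action(s): ", paste(miss, collapse = ", "))
  costs <- spec$costs[names(effects)]
  nb <- switch(spec$form,
    monetary = sweep(spec$wtp * effects, 2, costs, "-"),
    health   = sweep(effects, 2, costs / spec$wtp, "-"))
  output_draws(as.data.frame(nb), "decision")
}

# index of the action optimal under current information (max expected NB);
# ties broken to the lowest index with a warning
current_best_action <- function(nb) {
  enb <- colMeans(as.data.frame(nb))
  top <- which(enb == max(enb))
  if (length(top) > 1)
    warning("tie in expected net benefit between actions ",
            paste(names(enb)[top], collapse = ", "),
            "; choosing the first")
  top[1]
}

#' Per-draw opportunity benefit of perfect information
#'
#' For each parameter draw, the net benefit of the action we would choose
#' knowing \eqn{\theta} minus the net benefit of the action optimal under
#' current information (the one with the highest expected net benefit).
#' Every entry is nonnegative; its mean is the EVPI.
#'
#' @param nb An [output_draws()] of kind `"decision"`.
#' @return Numeric vector of length R.
#' @export
opportunity_benefit <- function(nb) {
  if (output_kind(nb) != "decision")
    stop("opportunity benefit is defined for decision problems")
  m <- unname(as.matrix(as.data.frame(nb)))
  a_star <- current_best_action(nb)
  apply(m, 1, max) - m[, a_star]
}

#' Expected value of perfect information
#'
#' For a decision problem, the expected net benefit under perfect
#' information minus the expected net benefit under current information:
#' \deqn{EVPI = E_\theta[NB_{a(\theta)}(\theta)] - \max_a E_\theta[NB_a(\theta)],}
#' estimated as the mean of the per-draw [opportunity_benefit()].  For an
#' estimation problem under squared-error loss, the EVPI is the variance of
#' the output's uncertainty distribution, estimated by the empirical
#' variance (divisor R - 1).
#'
#' @param outputs An [output_draws()] object of either kind.
#' @return A `voi_estimate` with a Monte Carlo standard error.
#' @examples
#' nb <- output_draws(data.frame(a1 = c(0, 0, 0, 0), a2 = c(-1, 3, -2, 4)))
#' evpi(nb)$value  # 0.75
#' @export
evpi <- function(outputs) {
  kind <- output_kind(outputs)
  if (kind == "decision") {
    ob <- opportunity_benefit(outputs)
    voi_estimate("EVPI", mean(ob), mc_se = stats::sd(ob) / sqrt(length(ob)),
                 meta = list(kind = "decision", n = length(ob)))
  } else {
    y <- as.numeric(outputs)
    voi_estimate("EVPI", stats::var(y), mc_se = var_se(y),
                 meta = list(kind = "estimation", n = length(y)))
  }
}
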