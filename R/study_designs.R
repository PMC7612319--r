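#' Define a study design for EVSI computation
#'
#' A study design couples a sampling model for the future data Z given the
#' model parameters with a summary statistic T(Z).  The `simulate` function
#' receives the full table of parameter draws and a sample size n, and must
#' return one summary per draw: a numeric vector of length R, or an R x q
#' matrix/data frame when the summary has q components.  It must consume
#' randomness only through R's RNG (so that a seed makes it reproducible)
#' and return a summary of constant dimension.
#'
#' The contract is validated on three probe draws: the simulator is run
#' twice under the same RNG state and must return identical, numeric,
#' fixed-dimension results.
#'
#' @param name Short name used in results and logs.
#' @param simulate `function(inputs, n)` as described above.
#' @param informs Character vector naming the parameters the study informs.
#' @return An object of class `"study_design"`.
#' @seealso [binary_design()], [custom_design()], [evsi()]
#' @export
study_design <- function(name, simulate, informs) {
  stopifnot(is.character(name), is.function(simulate), is.character(informs))
  structure(list(name = name, simulate = simulate, informs = informs),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design '", x$name, "', informing: ",
      paste(x$informs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Binary-outcome study design
#'
#' The simplest design: observe the number Z of events out of n
#' individuals, where the event probability is the named model parameter.
#' \eqn{Z^{(r)} \sim Binomial(n, p^{(r)})} and the summary statistic is
#' T(Z) = Z itself.
#'
#' @param informs Name of the probability parameter the study estimates.
#' @return A [study_design()].
#' @export
binary_design <- function(informs) {
  stopifnot(length(informs) == 1)
  sim <- function(inputs, n) {
    p <- inputs[[informs]]
    if (is.null(p)) stop("parameter '", informs, "' not found in the draws")
    if (any(p < 0 | p > 1))
      stop("parameter '", informs, "' has draws outside [0, 1]; ",
           "a binary design needs a probability")
    stats::rbinom(length(p), size = n, prob = p)
  }
  study_design("binary", sim, informs)
}

#' Wrap a user-supplied simulate-and-summarise function as a study design
#'
#' Use this when the study's summary statistic is not available in closed
#' form — for example, simulate the raw study data and return a maximum
#' likelihood estimate of the parameters of interest.  The contract is
#' checked on three probe draws: the function must be deterministic given
#' the RNG state and return a numeric summary of constant dimension.
#'
#' @inheritParams study_design
#' @param probe_inputs Optional small `parameter_draws` table used for
#'   validation; if supplied, the contract is verified at construction.
#' @return A [study_design()].
#' @export
custom_design <- function(name, simulate, informs, probe_inputs = NULL) {
  d <- study_design(name, simulate, informs)
  if (!is.null(probe_inputs))
    validate_design(d, probe_inputs)
  d
}

validate_design <- function(design, inputs, n = 5) {
  probe <- as.data.frame(inputs)[seq_len(min(3, nrow(inputs))), , drop = FALSE]
  old <- local_seed(99)
  t1 <- design$simulate(probe, n)
  set.seed(99)
  t2 <- design$simulate(probe, n)
  restore_seed(old)
  d1 <- if (is.null(dim(t1))) c(length(t1), 1L) else dim(as.matrix(t1))
  d2 <- if (is.null(dim(t2))) c(length(t2), 1L) else dim(as.matrix(t2))
  if (!is.numeric(as.matrix(t1)))
    stop("design '", design$name, "' returned a non-numeric summary")
  if (!identical(d1, d2) || !isTRUE(all.equal(as.matrix(t1), as.matrix(t2))))
    stop("design '", design$name, "' is not deterministic under a fixed ",
         "RNG state, or its summary dimension varies across draws")
  if (d1[1] != nrow(probe))
    stop("design '", design$name, "' must return one summary per draw")
  invisible(TRUE)
}

#' Effective sample size of a published proportion estimate
#'
#' Converts an estimated proportion (posterior mean m, standard error se)
#' into the sample size n of the hypothetical binary-outcome study whose
#' Beta posterior (under a vague Beta(0, 0) prior) has that mean and
#' standard deviation: \deqn{n = m(1 - m)/se^2 - 1.}  This prices imperfect
#' published information: the value of obtaining such an estimate is the
#' EVSI of a binary study with n observations.
#'
#' @param m Estimated proportion, in (0, 1).
#' @param se Standard error of the estimate; must not exceed
#'   \eqn{\sqrt{m(1-m)}} (otherwise the implied n is negative).
#' @return Integer effective sample size (rounded half-to-even, floored
#'   at 0).
#' @examples
#' ess_from_se(0.2, 0.1)    # 15
#' ess_from_se(0.2, 0.01)   # 1599
#' @export
ess_from_se <- function(m, se) {
  stopifnot(length(m) == 1, length(se) == 1)
  if (m <= 0 || m >= 1) stop("'m' must be strictly between 0 and 1")
  if (se <= 0) stop("'se' must be positive")
  if (se > sqrt(m * (1 - m)))
    stop("se = ", se, " is not below sqrt(m(1-m)) = ",
         signif(sqrt(m * (1 - m)), 4),
         ": the implied effective sample size would be negative")
  n <- m * (1 - m) / se^2 - 1
  max(0L, as.integer(round(n)))
}
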