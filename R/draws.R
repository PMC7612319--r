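#' Container for a Monte Carlo sample of model input parameters
#'
#' Wraps an R x P table of sampled parameter values, one row per draw and
#' one named column per scalar parameter, after validating it.  This is the
#' `inputs` object consumed by [evppi()], [evsi()] and the sensitivity
#' functions.
#'
#' @param values A data frame or matrix of numeric draws with unique column
#'   names, at least 2 rows, and no missing values.
#' @return A data frame of class `"parameter_draws"`.
#' @examples
#' theta <- parameter_draws(data.frame(mu = rlnorm(100), pi = rbeta(100, 2, 3)))
#' ndraws(theta)
#' @export
parameter_draws <- function(values) {
  values <- as.data.frame(values)
  if (nrow(values) < 2)
    stop("parameter draws need at least 2 rows, got ", nrow(values))
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("parameter columns must have unique names")
  if (!all(vapply(values, is.numeric, logical(1))))
    stop("all parameter columns must be numeric")
  if (anyNA(values))
    stop("parameter draws contain missing values")
  class(values) <- c("parameter_draws", "data.frame")
  values
}

#' Container for a Monte Carlo sample of model outputs
#'
#' For an estimation problem, a vector of sampled outputs
#' \eqn{y^{(r)} = f(\theta^{(r)})}; for a decision problem, an R x A table
#' of sampled net benefits, one column per action.
#'
#' @param values Numeric vector (estimation) or data frame / matrix with at
#'   least two named columns (decision).
#' @param kind `"estimation"` or `"decision"`.  Defaults to `"estimation"`
#'   for a vector and `"decision"` for a table.
#' @return An object of class `"output_draws"`: a numeric vector or a data
#'   frame, with attribute `kind`.
#' @examples
#' y  <- output_draws(rnorm(100))
#' nb <- output_draws(data.frame(status_quo = 0 * 1:100, policy = rnorm(100)))
#' @export
output_draws <- function(values, kind = NULL) {
  if (is.null(kind))
    kind <- if (is.null(dim(values))) "estimation" else "decision"
  kind <- match.arg(kind, c("estimation", "decision"))
  if (kind == "estimation") {
    values <- as.numeric(values)
    if (length(values) < 2) stop("need at least 2 output draws")
    if (anyNA(values)) stop("output draws contain missing values")
  } else {
    values <- as.data.frame(values)
    if (ncol(values) < 2)
      stop("a decision problem needs at least 2 actions (columns)")
    if (is.null(names(values)) || anyDuplicated(names(values)))
      stop("action columns must have unique names")
    if (!all(vapply(values, is.numeric, logical(1))) || anyNA(values))
      stop("net benefit columns must be numeric with no missing values")
  }
  structure(values, kind = kind,
            class = c("output_draws", class(values)))
}

#' @export
print.output_draws <- function(x, ...) {
  kind <- attr(x, "kind")
  if (kind == "estimation") {
    cat("Output draws (estimation problem), R =", length(x), "\n")
    print(utils::head(unclass(x)))
  } else {
    cat("Output draws (decision problem), R =", nrow(x),
        ", actions:", paste(names(x), collapse = ", "), "\n")
    print(utils::head(as.data.frame(x)))
  }
  invisible(x)
}

#' Number of Monte Carlo draws in a container
#' @param x A `parameter_draws` or `output_draws` object.
#' @return Integer number of draws R.
#' @export
ndraws <- function(x) {
  if (inherits(x, "output_draws") && attr(x, "kind") == "estimation")
    return(length(x))
  nrow(x)
}

output_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) stop("not an output_draws object")
  k
}

check_aligned <- function(outputs, inputs) {
  if (ndraws(outputs) != ndraws(inputs))
    stop("outputs have ", ndraws(outputs), " draws but inputs have ",
         ndraws(inputs), "; the two samples must come from the same ",
         "Monte Carlo run")
  invisible(TRUE)
}

#' Construct a value-of-information estimate
#'
#' Internal constructor used by all estimators.  Negative raw values, which
#' can arise from Monte Carlo noise, are clipped to zero; the raw value is
#' retained in `meta$raw` and the clipping is flagged.
#'
#' @param measure One of `"EVPI"`, `"EVPPI"`, `"EVSI"`, `"ENBS"`.
#' @param value Numeric estimate.
#' @param mc_se Monte Carlo standard error, or `NA`.
#' @param meta Named list of method details.
#' @return Object of class `"voi_estimate"`.
#' @keywords internal
voi_estimate <- function(measure, value, mc_se = NA_real_, meta = list()) {
  measure <- match.arg(measure, c("EVPI", "EVPPI", "EVSI", "ENBS"))
  meta$raw <- value
  clipped <- FALSE
  if (measure != "ENBS" && is.finite(value) && value < 0) {
    value <- 0
    clipped <- TRUE
  }
  meta$clipped <- clipped
  structure(list(measure = measure, value = value,
                 mc_se = mc_se, meta = meta),
            class = "voi_estimate")
}

#' @export
print.voi_estimate <- function(x, ...) {
  cat(x$measure, ": ", format(x$value, digits = 6), sep = "")
  if (!is.na(x$mc_se)) cat("  (MC SE ", format(x$mc_se, digits = 3), ")", sep = "")
  if (isTRUE(x$meta$clipped))
    cat("  [negative raw estimate ", format(x$meta$raw, digits = 3),
        " clipped to 0]", sep = "")
  cat("\n")
  if (!is.null(x$meta$method)) cat("  method:", x$meta$method, "\n")
  invisible(x)
}

#' @export
as.numeric.voi_estimate <- function(x, ...) x$value

#' Serialize a VoI estimate to JSON
#' @param x A `voi_estimate`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
voi_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "voi_estimate"))
  obj <- list(schema_version = 1L, measure = x$measure, value = x$value,
              mc_se = if (is.na(x$mc_se)) NULL else x$mc_se,
              meta = x$meta[setdiff(names(x$meta), "fit")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

logit <- function(p) log(p) - log1p(-p)
expit <- function(x) 1 / (1 + exp(-x))

# standard error of an empirical variance, from fourth moments
var_se <- function(y) {
  n <- length(y)
  m <- mean(y)
  s2 <- stats::var(y)
  m4 <- mean((y - m)^4)
  sqrt(pmax(0, m4 - s2^2 * (n - 3) / (n - 1)) / n)
}
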