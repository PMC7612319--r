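#' Fit a flexible conditional-mean regression (emulator)
#'
#' Fits \eqn{y^{(r)} = h(x^{(r)}) + \epsilon^{(r)}}, \eqn{\epsilon \sim
#' N(0, \sigma^2)}, with a flexible nonparametric mean function h.  This is
#' the engine behind regression-based EVPPI and EVSI: the variance of the
#' fitted values estimates the variance of the output explained by the
#' predictors, and the residual variance estimates what would remain after
#' learning them.
#'
#' Backends:
#' \describe{
#'   \item{`spline_gam`}{Penalized cubic regression splines via
#'     [mgcv::gam()], smoothing parameter by GCV.  A single predictor uses
#'     one smooth term (basis dimension `basis_dim`, default
#'     `min(10, floor(R/50))`); two predictors use a tensor-product smooth;
#'     three or four use additive smooths.  A single predictor with at most
#'     5 distinct values (e.g. a small-count study summary statistic) is
#'     fitted by its exact group means.}
#'   \item{`adaptive_splines`}{Multivariate adaptive regression splines:
#'     forward selection of hinge-function products (max interaction
#'     degree 2) up to `max_terms` basis terms, then backward pruning by
#'     generalized cross-validation.}
#'   \item{`gaussian_process`}{Gaussian process regression with a
#'     squared-exponential kernel, per-dimension lengthscales and a nugget,
#'     hyperparameters by marginal-likelihood maximization.  For
#'     tractability the process is trained on a random subset of
#'     `gp_subset` draws (default `min(R, 2000)`) and fitted values are
#'     computed at all R draws.}
#'   \item{`auto`}{Fits all three on a seeded 80/20 train/validation split,
#'     picks the backend with the lowest held-out mean squared error, and
#'     refits it on the full sample.}
#' }
#'
#' Predictors are standardized to zero mean and unit variance internally.
#' The returned residual variance is the empirical variance (divisor R - 1)
#' of the residuals, so that `var(y) ~ var(fitted) + resid_var` (law of
#' total variance) up to the small non-orthogonality of penalized fits.
#'
#' @param x Data frame or matrix of predictors (R rows, p columns).
#' @param y Numeric response vector of length R.
#' @param method `"spline_gam"`, `"adaptive_splines"`,
#'   `"gaussian_process"`, or `"auto"`.
#' @param options Named list: `basis_dim`, `max_terms`, `gp_subset`,
#'   `seed` (used for the GP subset and the auto split).
#' @return Object of class `"fitted_surface"` with elements `fitted`,
#'   `resid_var`, `method`, `diagnostics`.
#' @examples
#' x <- runif(500); y <- sin(2 * pi * x) + rnorm(500, 0, 0.3)
#' fit <- fit_flexible_mean(data.frame(x = x), y)
#' fit$resid_var  # close to 0.09
#' @export
fit_flexible_mean <- function(x, y,
                              method = c("spline_gam", "adaptive_splines",
                                         "gaussian_process", "auto"),
                              options = list()) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  if (!all(vapply(x, is.numeric, logical(1)))) stop("predictors must be numeric")
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(x) != n) stop("x has ", nrow(x), " rows but y has length ", n)
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("predictor(s) ", paste(names(x)[sds == 0], collapse = ", "),
         " are constant: the predictor matrix is rank-deficient")
  opts <- utils::modifyList(
    list(basis_dim = max(3, min(10, floor(n / 50))),
         max_terms = 21, gp_subset = 2000, seed = 1), options)

  ctr <- vapply(x, mean, numeric(1))
  xs <- as.data.frame(scale(x, center = ctr, scale = sds))
  # safe internal names: user columns may shadow base objects in formulas
  names(xs) <- paste0(".x", seq_along(xs))
  if (method == "auto") {
    method <- select_backend(xs, y, opts)
  }
  fit <- switch(method,
    spline_gam       = fit_gam_backend(xs, y, opts),
    adaptive_splines = fit_mars_backend(xs, y, opts),
    gaussian_process = fit_gp_backend(xs, y, opts))
  res <- y - fit$fitted
  structure(list(fitted = fit$fitted,
                 resid_var = sum((res - mean(res))^2) / (n - 1),
                 method = method,
                 diagnostics = fit$diagnostics,
                 model = fit$model,
                 x_center = ctr, x_scale = sds,
                 x_range = lapply(xs, range), xnames = names(x)),
            class = "fitted_surface")
}

#' @export
print.fitted_surface <- function(x, ...) {
  cat("Flexible regression surface (", x$method, "), R = ",
      length(x$fitted), ", p = ", length(x$xnames), "\n",
      "  var(fitted) = ", format(stats::var(x$fitted), digits = 5),
      ", residual variance = ", format(x$resid_var, digits = 5), "\n",
      sep = "")
  invisible(x)
}

#' Predict from a fitted surface
#'
#' Evaluates the fitted mean function at new predictor values.  Points
#' outside the training support are extrapolations and trigger a warning.
#'
#' @param fit A `"fitted_surface"` from [fit_flexible_mean()].
#' @param xnew Data frame (or vector for p = 1) of new predictor values.
#' @return Numeric vector of predictions.
#' @export
predict_surface <- function(fit, xnew) {
  stopifnot(inherits(fit, "fitted_surface"))
  if (is.null(dim(xnew))) {
    if (length(fit$xnames) != 1)
      stop("fit has ", length(fit$xnames), " predictors; supply a data frame")
    xnew <- stats::setNames(data.frame(xnew), fit$xnames)
  }
  xnew <- as.data.frame(xnew)
  if (!all(fit$xnames %in% names(xnew)))
    stop("xnew is missing predictor(s): ",
         paste(setdiff(fit$xnames, names(xnew)), collapse = ", "))
  xnew <- xnew[fit$xnames]
  xs <- as.data.frame(scale(xnew, center = fit$x_center, scale = fit$x_scale))
  names(xs) <- paste0(".x", seq_along(xs))
  outside <- mapply(function(col, rg) any(col < rg[1] | col > rg[2]),
                    xs, fit$x_range)
  if (any(outside))
    warning("predicting outside the training range of: ",
            paste(fit$xnames[outside], collapse = ", "))
  m <- fit$model
  switch(m$backend,
    gam   = as.numeric(stats::predict(m$gam, newdata = xs)),
    means = {
      lev <- m$levels
      idx <- vapply(xs[[1]], function(v) which.min(abs(lev - v)), integer(1))
      m$means[idx]
    },
    mars = as.numeric(mars_basis(xs, m$terms) %*% m$coef),
    gp   = gp_posterior_mean(xs, m))
}

## ---- backend selection (the "auto" predictive-training procedure) ----

select_backend <- function(xs, y, opts) {
  n <- length(y)
  old <- local_seed(opts$seed)
  on.exit(restore_seed(old))
  idx <- sample.int(n, size = floor(0.8 * n))
  tr_x <- xs[idx, , drop = FALSE]; tr_y <- y[idx]
  va_x <- xs[-idx, , drop = FALSE]; va_y <- y[-idx]
  o2 <- opts; o2$gp_subset <- min(opts$gp_subset, 500)
  mse <- vapply(c("spline_gam", "adaptive_splines", "gaussian_process"),
    function(mth) {
      f <- tryCatch(switch(mth,
             spline_gam       = fit_gam_backend(tr_x, tr_y, o2),
             adaptive_splines = fit_mars_backend(tr_x, tr_y, o2),
             gaussian_process = fit_gp_backend(tr_x, tr_y, o2)),
           error = function(e) NULL)
      if (is.null(f)) return(Inf)
      pr <- tryCatch(predict_backend_std(f, va_x), error = function(e) NULL)
      if (is.null(pr)) return(Inf)
      mean((va_y - pr)^2)
    }, numeric(1))
  names(mse)[which.min(mse)]
}

# predict on already-standardized x, for internal validation only
predict_backend_std <- function(fit, xs) {
  m <- fit$model
  switch(m$backend,
    gam   = as.numeric(stats::predict(m$gam, newdata = xs)),
    means = {
      idx <- vapply(xs[[1]], function(v) which.min(abs(m$levels - v)), integer(1))
      m$means[idx]
    },
    mars  = as.numeric(mars_basis(xs, m$terms) %*% m$coef),
    gp    = gp_posterior_mean(xs, m))
}

## ---- penalized spline backend (mgcv) ----

fit_gam_backend <- function(xs, y, opts) {
  p <- ncol(xs)
  n <- length(y)
  vn <- names(xs)
  if (p == 1) {
    ux <- sort(unique(xs[[1]]))
    if (length(ux) <= 5) {
      # few distinct predictor values: conditional mean = group means
      grp <- match(xs[[1]], ux)
      means <- vapply(split(y, grp), mean, numeric(1))
      return(list(fitted = means[grp],
                  diagnostics = list(discrete = TRUE, n_levels = length(ux)),
                  model = list(backend = "means", levels = ux, means = means)))
    }
    k <- max(3, min(opts$basis_dim, length(ux) - 1))
    fml <- stats::as.formula(sprintf("y ~ s(%s, bs = 'cr', k = %d)", vn[1], k))
  } else if (p == 2) {
    fml <- stats::as.formula(sprintf("y ~ te(%s, %s)", vn[1], vn[2]))
  } else if (p <= 4) {
    k <- max(3, min(opts$basis_dim, 8))
    fml <- stats::as.formula(paste("y ~",
      paste(sprintf("s(%s, bs = 'cr', k = %d)", vn, k), collapse = " + ")))
  } else {
    stop("spline_gam supports at most 4 predictors; use adaptive_splines ",
         "or gaussian_process for p = ", p)
  }
  dat <- cbind(y = y, xs)
  g <- mgcv::gam(fml, data = dat, method = "GCV.Cp")
  list(fitted = as.numeric(stats::fitted(g)),
       diagnostics = list(edf = sum(g$edf), gcv = g$gcv.ubre),
       model = list(backend = "gam", gam = g))
}

## ---- adaptive regression splines backend (hinge products, GCV pruning) ----

# evaluate the basis described by `terms` (a list of lists of
# (var, knot, sign) components; empty list = intercept) at standardized x
mars_basis <- function(xs, terms) {
  n <- nrow(xs)
  B <- matrix(1, n, length(terms))
  for (j in seq_along(terms)) {
    for (cmp in terms[[j]])
      B[, j] <- B[, j] * pmax(0, cmp$sign * (xs[[cmp$var]] - cmp$knot))
  }
  B
}

mars_gcv <- function(rss, n, nterms) {
  cm <- nterms + 3 * (nterms - 1)  # effective parameters, Friedman penalty 3
  if (cm >= n) return(Inf)
  (rss / n) / (1 - cm / n)^2
}

fit_mars_backend <- function(xs, y, opts) {
  n <- length(y); p <- ncol(xs)
  max_terms <- opts$max_terms
  max_degree <- 2L
  # candidate knots: interior quantiles of each standardized predictor
  knots <- lapply(xs, function(col) {
    ux <- unique(col)
    nk <- min(15, length(ux) - 1)
    if (nk < 1) return(numeric(0))
    unique(as.numeric(stats::quantile(col, probs = seq_len(nk) / (nk + 1),
                                      type = 1)))
  })
  hinges <- lapply(seq_len(p), function(d) {
    kd <- knots[[d]]
    if (!length(kd)) return(NULL)
    H <- cbind(pmax(outer(xs[[d]], kd, "-"), 0),
               pmax(-outer(xs[[d]], kd, "-"), 0))
    attr(H, "spec") <- data.frame(var = d, knot = rep(kd, 2),
                                  sign = rep(c(1, -1), each = length(kd)))
    H
  })
  terms <- list(list())           # start with the intercept
  B <- matrix(1, n, 1)
  tss <- sum((y - mean(y))^2)
  repeat {
    if (ncol(B) >= max_terms) break
    qrB <- qr(B)
    Q <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
    yperp <- y - Q %*% crossprod(Q, y)
    best <- list(score = 0)
    for (parent in seq_along(terms)) {
      deg <- length(terms[[parent]])
      if (deg >= max_degree) next
      used <- vapply(terms[[parent]], `[[`, numeric(1), "var")
      for (d in setdiff(seq_len(p), used)) {
        H <- hinges[[d]]
        if (is.null(H)) next
        C <- if (deg == 0) H else H * B[, parent]
        Cperp <- C - Q %*% crossprod(Q, C)
        den <- colSums(Cperp^2)
        num <- as.numeric(crossprod(Cperp, yperp))
        sc <- ifelse(den > 1e-10 * n, num^2 / den, -Inf)
        j <- which.max(sc)
        if (sc[j] > best$score)
          best <- list(score = sc[j], parent = parent, var = d, j = j,
                       spec = attr(H, "spec")[j, ])
      }
    }
    if (best$score < 1e-9 * tss) break
    # add the selected hinge and its reflected partner
    for (sg in c(best$spec$sign, -best$spec$sign)) {
      cmp <- list(var = best$var, knot = best$spec$knot, sign = sg)
      newterm <- c(terms[[best$parent]], list(cmp))
      col <- B[, best$parent] * pmax(0, sg * (xs[[best$var]] - cmp$knot))
      if (sum(col^2) > 1e-10 * n && ncol(B) < max_terms) {
        terms <- c(terms, list(newterm))
        B <- cbind(B, col)
      }
    }
  }
  # backward pruning by GCV
  fit_subset <- function(cols) {
    f <- stats::lm.fit(B[, cols, drop = FALSE], y)
    sum(f$residuals^2)
  }
  active <- seq_along(terms)
  best_set <- active
  best_gcv <- mars_gcv(fit_subset(active), n, length(active))
  while (length(active) > 1) {
    cand <- setdiff(active, 1)   # never drop the intercept
    gcvs <- vapply(cand, function(j) {
      sub <- setdiff(active, j)
      mars_gcv(fit_subset(sub), n, length(sub))
    }, numeric(1))
    active <- setdiff(active, cand[which.min(gcvs)])
    if (min(gcvs) < best_gcv) {
      best_gcv <- min(gcvs)
      best_set <- active
    }
  }
  terms <- terms[best_set]
  Bf <- B[, best_set, drop = FALSE]
  f <- stats::lm.fit(Bf, y)
  cf <- f$coefficients
  keep <- !is.na(cf)
  terms <- terms[keep]
  cf <- cf[keep]
  fitted <- as.numeric(Bf[, keep, drop = FALSE] %*% cf)
  list(fitted = fitted,
       diagnostics = list(n_terms = length(terms), gcv = best_gcv),
       model = list(backend = "mars", terms = terms, coef = cf))
}

## ---- Gaussian process backend (SE-ARD kernel + nugget, ML hyperpars) ----

gp_negloglik <- function(u, D2, ys, want_grad = FALSE) {
  p <- length(D2)
  l2 <- exp(2 * u[seq_len(p)]); s2 <- exp(u[p + 1]); nug <- exp(u[p + 2])
  m <- length(ys)
  S <- Reduce(`+`, Map(function(D, l) D / l, D2, l2))
  Kse <- s2 * exp(-0.5 * S)
  K <- Kse + diag(nug, m)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, p + 2)))
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  nll <- 0.5 * sum(ys * alpha) + sum(log(diag(ch))) + 0.5 * m * log(2 * pi)
  out <- list(value = as.numeric(nll))
  if (want_grad) {
    Kinv <- chol2inv(ch)
    W <- tcrossprod(alpha) - Kinv           # so dNLL/dpsi = -0.5 tr(W dK)
    g <- numeric(p + 2)
    for (d in seq_len(p))
      g[d] <- -0.5 * sum(W * (Kse * (D2[[d]] / l2[d])))
    g[p + 1] <- -0.5 * sum(W * Kse)
    g[p + 2] <- -0.5 * nug * sum(diag(W))
    out$grad <- g
  }
  out
}

fit_gp_backend <- function(xs, y, opts) {
  n <- length(y); p <- ncol(xs)
  m <- min(n, opts$gp_subset)
  old <- local_seed(opts$seed)
  sub <- if (m < n) sort(sample.int(n, m)) else seq_len(n)
  restore_seed(old)
  Xs <- as.matrix(xs)[sub, , drop = FALSE]
  my <- mean(y[sub]); sy <- stats::sd(y[sub])
  if (sy == 0)
    return(list(fitted = rep(mean(y), n),
                diagnostics = list(constant = TRUE),
                model = list(backend = "gp", const = mean(y))))
  ys <- (y[sub] - my) / sy
  D2 <- lapply(seq_len(p), function(d) outer(Xs[, d], Xs[, d], "-")^2)
  fn <- function(u) gp_negloglik(u, D2, ys)$value
  gr <- function(u) gp_negloglik(u, D2, ys, want_grad = TRUE)$grad
  u0 <- c(rep(0, p), 0, log(0.1))
  opt <- stats::optim(u0, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(-4, p), -8, -12),
                      upper = c(rep(4, p), 4, 2),
                      control = list(maxit = 100))
  u <- opt$par
  l2 <- exp(2 * u[seq_len(p)]); s2 <- exp(u[p + 1]); nug <- exp(u[p + 2])
  S <- Reduce(`+`, Map(function(D, l) D / l, D2, l2))
  K <- s2 * exp(-0.5 * S) + diag(nug, m)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  model <- list(backend = "gp", X = Xs, alpha = alpha,
                lengthscales = sqrt(l2), s2 = s2, nugget = nug,
                y_center = my, y_scale = sy)
  list(fitted = gp_posterior_mean(xs, model),
       diagnostics = list(lengthscales = sqrt(l2), signal_var = s2,
                          nugget = nug, subset = m,
                          converged = opt$convergence == 0),
       model = model)
}

gp_posterior_mean <- function(xs, model) {
  if (!is.null(model$const)) return(rep(model$const, nrow(xs)))
  Xn <- as.matrix(xs)
  S <- matrix(0, nrow(Xn), nrow(model$X))
  for (d in seq_len(ncol(Xn)))
    S <- S + outer(Xn[, d], model$X[, d], "-")^2 / model$lengthscales[d]^2
  Kstar <- model$s2 * exp(-0.5 * S)
  model$y_center + model$y_scale * as.numeric(Kstar %*% model$alpha)
}

## ---- seed handling: use a local RNG stream, restore the caller's ----

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
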