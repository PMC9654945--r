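#' Degrees-of-freedom-adjusted fit metrics
#'
#' Computes the two reporting metrics used throughout the package:
#' \deqn{RMSE = \sqrt{\sum (y_i - \hat y_i)^2 / (n - p)}}
#' \deqn{R^2 = 1 - \frac{n-1}{n-p}
#'   \frac{\sum (y_i - \hat y_i)^2}{\sum (y_i - \bar y)^2}}
#' with \code{n} observations and \code{p} fitted parameters. With
#' \code{p = 1} this reduces to the classical unadjusted coefficient of
#' determination; with \code{p > 1} it is strictly smaller whenever the
#' residuals are not all zero.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param p number of fitted parameters, < length(observed).
#' @return a \linkS4class{FitMetrics}.
#' @examples
#' fitMetrics(1:5, c(1.1, 1.9, 3.2, 3.8, 5.1), p = 2)
#' @export
fitMetrics <- function(observed, predicted, p) {
  .assertFiniteNumeric(observed, "observed")
  .assertFiniteNumeric(predicted, "predicted")
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  n <- length(observed)
  p <- as.integer(p)
  if (n <= p)
    stop("degrees-of-freedom error: need n > p (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("degenerate data: observed series has zero variance", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  new("FitMetrics",
      r2 = 1 - (n - 1) / (n - p) * sse / sst,
      rmse = sqrt(sse / (n - p)),
      n = n, p = p)
}

#' Pearson correlation between a fitted curve and a reference series
#'
#' Used to report how closely a sensor-fitted curve tracks the
#' plate-count log series sampled on the same grid.
#'
#' @param fitted,reference numeric vectors, equal length >= 3, each with
#'   nonzero variance.
#' @return correlation in [-1, 1].
#' @export
curveCorrelation <- function(fitted, reference) {
  .assertFiniteNumeric(fitted, "fitted")
  .assertFiniteNumeric(reference, "reference")
  if (length(fitted) != length(reference) || length(fitted) < 3L)
    stop("need equal-length series with >= 3 points", call. = FALSE)
  if (var(fitted) == 0 || var(reference) == 0)
    stop("degenerate data: a series has zero variance", call. = FALSE)
  cor(fitted, reference)
}

## default box constraints: levels within the observed range +/- one
## full span (slow curves end well short of their asymptote, so nMax
## can sit far above the last observation), muMax in (1e-4, 1], lag in
## [0, max time]
.defaultBounds <- function(times, values) {
  rng <- range(values)
  span <- diff(rng)
  list(lower = c(n0 = rng[1] - span, nMax = rng[1] - span,
                 muMax = 1e-4, lag = 0),
       upper = c(n0 = rng[2] + span, nMax = rng[2] + span,
                 muMax = 1, lag = max(times)))
}

## data-driven start: endpoints for the levels, steepest finite-difference
## slope for muMax, slope location minus 1/muMax for the lag
.heuristicStart <- function(times, values, lower, upper) {
  n <- length(values)
  sl <- diff(values) / diff(times)
  i <- which.max(abs(sl))
  span <- abs(values[n] - values[1])
  mu0 <- if (span > 0) abs(sl[i]) * exp(1) / span else 0.01
  mu0 <- min(max(mu0, lower[3] * 1.01), upper[3])
  lag0 <- min(max(times[i] - 1 / mu0, 0), upper[4])
  pmin(pmax(c(values[1], values[n], mu0, lag0), lower), upper)
}

.runRestart <- function(fn, start, lower, upper, tolerance) {
  fit <- try(minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = tolerance, ptol = 1e-12)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  sse <- sum(fit$fvec^2)
  if (!is.finite(sse)) return(NULL)
  list(par = fit$par, sse = sse, info = fit$info)
}

#' Fit one primary growth model by multi-start bounded least squares
#'
#' Minimises the residual sum of squares over the box-constrained
#' parameter space with a Levenberg-Marquardt solver started once from a
#' data-driven heuristic and \code{nRestarts - 1} times from a seeded
#' Latin-hypercube over the bounds; the best restart is returned.
#' Degenerate inputs (constant series) and an all-restarts failure are
#' reported as errors. Two calls with the same options produce
#' bit-identical results.
#'
#' @param series a \linkS4class{CurveSeries} with >= 5 points.
#' @param kind one of \code{modelKinds()}.
#' @param options a \linkS4class{FitOptions}.
#' @param reference optional numeric series on the same grid; when
#'   given, the Pearson correlation between the fitted curve and this
#'   reference is recorded in the result.
#' @return a \linkS4class{FitResult} with training metrics at p = 4.
#' @examples
#' p <- growthParams(4, 6, 0.06, 50)
#' s <- evaluateCurve("logistic", p, seq(0, 168, 12))
#' fitGrowth(s, "logistic", fitOptions(nRestarts = 8))
#' @export
fitGrowth <- function(series, kind, options = fitOptions(),
                      reference = NULL) {
  kind <- .matchKind(kind)
  stopifnot(is(series, "CurveSeries"), is(options, "FitOptions"))
  validObject(series)
  times <- series@times
  values <- series@values
  if (length(times) < 5L)
    stop("need >= 5 time points to fit 4 parameters", call. = FALSE)
  .assertFiniteNumeric(values, "series values")
  if (var(values) == 0)
    stop("degenerate data: series has zero variance", call. = FALSE)

  b <- if (length(options@bounds)) options@bounds
       else .defaultBounds(times, values)
  lower <- b$lower
  upper <- b$upper
  f <- .curveFun(kind)
  resfn <- function(p) {
    v <- f(times, p[1], p[2], p[3], p[4])
    if (any(!is.finite(v)) || p[1] == p[2]) rep(1e6, length(values))
    else values - v
  }

  starts <- list(.heuristicStart(times, values, lower, upper))
  if (options@nRestarts > 1L) {
    grid <- .withSeed(options@seed,
                      lhs::randomLHS(options@nRestarts - 1L, 4))
    for (j in seq_len(nrow(grid)))
      starts[[j + 1L]] <- lower + grid[j, ] * (upper - lower)
  }

  best <- NULL
  for (s in starts) {
    cand <- .runRestart(resfn, s, lower, upper, options@tolerance)
    if (!is.null(cand) && (is.null(best) || cand$sse < best$sse))
      best <- cand
  }
  if (is.null(best))
    stop("convergence error: all ", options@nRestarts,
         " restarts failed for model '", kind, "'", call. = FALSE)

  pars <- best$par
  ## guard against a degenerate nMax == n0 corner of the box
  if (pars[2] == pars[1]) pars[2] <- pars[1] + 1e-9
  params <- growthParams(pars[1], pars[2], max(pars[3], 1e-12), max(pars[4], 0))
  fitted <- f(times, params@n0, params@nMax, params@muMax, params@lag)
  train <- fitMetrics(values, fitted, p = 4L)
  r <- if (is.null(reference)) numeric()
       else curveCorrelation(fitted, reference)
  new("FitResult", kind = kind, params = params, train = train, test = NULL,
      r = r, sse = best$sse, converged = best$info %in% 1:4,
      restartsUsed = options@nRestarts)
}

#' Fit all four primary models to one series
#'
#' Fits each model kind to the same series and returns the results
#' sorted by adjusted R-squared (descending), ties broken first by lower
#' RMSE and then by the conventional model order. Individual model
#' failures are carried as failure records so a report is never silent.
#'
#' @inheritParams fitGrowth
#' @return named list of \linkS4class{FitResult} (or, for a failed
#'   model, a list with elements \code{kind} and \code{error}), best
#'   fit first.
#' @export
fitAll <- function(series, options = fitOptions(), reference = NULL) {
  fits <- lapply(modelKinds(), function(k) {
    tryCatch(fitGrowth(series, k, options, reference),
             error = function(e) list(kind = k, error = conditionMessage(e)))
  })
  names(fits) <- modelKinds()
  ok <- vapply(fits, function(f) is(f, "FitResult"), TRUE)
  if (!any(ok)) return(fits)
  scored <- fits[ok]
  key <- order(-vapply(scored, r2, 0), vapply(scored, rmse, 0),
               match(vapply(scored, modelKind, ""), modelKinds()))
  c(scored[key], fits[!ok])
}

.panelChannelMeans <- function(panel, channel) {
  if (!channel %in% rownames(panel))
    stop("channel '", channel, "' not present in panel", call. = FALSE)
  v <- SummarizedExperiment::assay(panel, "response")[channel, ]
  tt <- SummarizedExperiment::colData(panel)$time_h
  means <- tapply(v, tt, mean)
  times <- as.numeric(names(means))
  o <- order(times)
  list(times = times[o], means = as.numeric(means)[o])
}

#' Fit a model on training replicates and validate on held-out ones
#'
#' Reduces both splits to per-time means, fits the model to the training
#' means, then evaluates the trained curve (no refit) on the testing
#' means; both metric sets use p = 4 since the same four parameters
#' generated both predictions.
#'
#' @param trainPanel,testPanel \linkS4class{ReplicatePanel} objects
#'   sharing one time grid.
#' @param channel the channel to extract from both panels.
#' @param kind one of \code{modelKinds()}.
#' @param options a \linkS4class{FitOptions}.
#' @param reference optional per-time reference series for the reported
#'   curve correlation.
#' @return a \linkS4class{FitResult} with both train and test metrics.
#' @export
fitWithValidation <- function(trainPanel, testPanel, channel, kind,
                              options = fitOptions(), reference = NULL) {
  tr <- .panelChannelMeans(trainPanel, channel)
  te <- .panelChannelMeans(testPanel, channel)
  if (length(tr$times) != length(te$times) ||
      any(abs(tr$times - te$times) > 1e-9))
    stop("alignment error: training and testing time grids differ",
         call. = FALSE)
  if (length(tr$times) < 5L)
    stop("need >= 5 training times", call. = FALSE)
  fit <- fitGrowth(curveSeries(tr$times, tr$means), kind, options, reference)
  predicted <- .curveValues(fit@kind, fit@params, te$times)
  fit@test <- fitMetrics(te$means, predicted, p = 4L)
  fit
}
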