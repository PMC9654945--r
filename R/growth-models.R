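#' The four primary growth models
#'
#' Returns the closed enumeration of supported model kinds, in the
#' conventional reporting order.
#'
#' @return character vector
#'   \code{c("modified_gompertz", "logistic", "huang", "baranyi")}.
#' @export
modelKinds <- function() c("modified_gompertz", "logistic", "huang", "baranyi")

.matchKind <- function(kind) {
  match.arg(kind, modelKinds())
}

## ---------------------------------------------------------------------------
## Model equations (canonical explicit forms)
##
## Modified Gompertz (Zwietering):
##   N(t) = N0 + dN * exp(-exp(muMax*e/|dN| * (lag - t) + 1)),  dN = Nmax-N0.
##   The slope factor uses |dN| so that a declining response (Nmax < N0,
##   as gas-sensor channels are) keeps the sigmoid monotone towards Nmax
##   with muMax > 0.
## Logistic (four-parameter):
##   N(t) = N0 + dN / (1 + exp(muMax * (lag - t)))
## Huang:
##   B(t) = t + (1/4) ln[(1 + e^{-4(t-lag)}) / (1 + e^{4 lag})]
##   N(t) = Nmax - log1p((e^{dN} - 1) e^{-muMax B(t)})
##   (algebraically identical to N0 + Nmax - ln[e^N0 + (e^Nmax - e^N0)
##    e^{-muMax B}] but stable for sensor-scale levels; B(0) = 0 gives
##    N(0) = N0 exactly.)
## Baranyi-Roberts (explicit form, h0 = muMax * lag):
##   A(t) = t + (1/muMax) ln(e^{-muMax t} + e^{-h0} - e^{-muMax t - h0})
##   N(t) = N0 + muMax A(t) - ln[1 + (e^{muMax A(t)} - 1) e^{-(Nmax-N0)}]
## ---------------------------------------------------------------------------

.curveModifiedGompertz <- function(t, n0, nmax, mu, lag) {
  d <- nmax - n0
  n0 + d * exp(-exp(mu * exp(1) / abs(d) * (lag - t) + 1))
}

.curveLogistic <- function(t, n0, nmax, mu, lag) {
  n0 + (nmax - n0) / (1 + exp(mu * (lag - t)))
}

.curveHuang <- function(t, n0, nmax, mu, lag) {
  B <- t + 0.25 * (.log1pexp(-4 * (t - lag)) - .log1pexp(4 * lag))
  nmax - log1p((exp(nmax - n0) - 1) * exp(-mu * B))
}

.curveBaranyi <- function(t, n0, nmax, mu, lag) {
  h0 <- mu * lag
  A <- t + .logSumBaranyi(mu * t, h0) / mu
  m <- mu * A
  ## log(1 + (e^m - 1) e^{-d}) = log(1 + e^{m-d} - e^{-d}), m >= 0
  d <- nmax - n0
  n0 + m - .log1pExpDiff(m - d, -d)
}

.curveFun <- function(kind) {
  switch(kind,
         modified_gompertz = .curveModifiedGompertz,
         logistic = .curveLogistic,
         huang = .curveHuang,
         baranyi = .curveBaranyi)
}

#' Evaluate a primary growth model on a time grid
#'
#' All four curves run monotonically from (near) \code{n0} at \code{t =
#' 0} to \code{nMax} as \code{t} grows; with \code{nMax < n0} they
#' decline, which is how falling sensor responses are modelled without
#' negating the data. The Huang curve passes through \code{n0} exactly
#' at \code{t = 0}; the other three start within their lag behaviour of
#' it.
#'
#' @param kind one of \code{modelKinds()}.
#' @param params a \linkS4class{GrowthParams}.
#' @param times finite, non-negative hours (need not be a grid).
#' @return a \linkS4class{CurveSeries} when \code{times} is strictly
#'   increasing, otherwise the bare numeric vector of levels.
#' @examples
#' p <- growthParams(3.992, 5.341, 0.062, 108.4)
#' evaluateCurve("logistic", p, seq(0, 168, 12))
#' @export
evaluateCurve <- function(kind, params, times) {
  kind <- .matchKind(kind)
  stopifnot(is(params, "GrowthParams"))
  validObject(params)
  .assertFiniteNumeric(times, "times")
  if (any(times < 0))
    stop("invalid input: times must be >= 0", call. = FALSE)
  vals <- .curveFun(kind)(times, params@n0, params@nMax,
                          params@muMax, params@lag)
  if (length(times) > 1L && all(diff(times) > 0))
    curveSeries(times, vals)
  else
    vals
}

.curveValues <- function(kind, params, times) {
  .curveFun(kind)(times, params@n0, params@nMax, params@muMax, params@lag)
}

#' Time at which a growth curve crosses a threshold
#'
#' Smallest \code{t >= 0} with \code{curve(t) == threshold}, located by
#' bisection on the monotone curve. With the conventional 5 Log CFU/mL
#' spoilage limit this is the shelf-life estimate of the fitted series.
#'
#' Thresholds at or beyond the starting level return 0 (the sample is
#' already there); thresholds at or beyond the asymptote \code{nMax}
#' are never reached and return \code{NA}.
#'
#' @param kind one of \code{modelKinds()}.
#' @param params a \linkS4class{GrowthParams}.
#' @param threshold level in the units of the curve.
#' @param tol absolute bisection tolerance on time (h).
#' @return hours, or \code{NA_real_} when the threshold is unreachable.
#' @examples
#' p <- growthParams(3.992, 5.341, 0.062, 108.4)
#' shelfLifeTime("logistic", p, 5)  # ~125.9 h
#' @export
shelfLifeTime <- function(kind, params, threshold, tol = 1e-9) {
  kind <- .matchKind(kind)
  stopifnot(is(params, "GrowthParams"))
  validObject(params)
  if (length(threshold) != 1L || !is.finite(threshold))
    stop("invalid input: threshold must be a finite scalar", call. = FALSE)
  increasing <- params@nMax > params@n0
  f <- function(t) .curveValues(kind, params, t)
  start <- f(0)
  ## already at/past the threshold at t = 0
  if ((increasing && threshold <= start) || (!increasing && threshold >= start))
    return(0)
  ## asymptote never attained
  if ((increasing && threshold >= params@nMax) ||
      (!increasing && threshold <= params@nMax))
    return(NA_real_)
  upper <- max(params@lag, 1)
  crossed <- function(t) if (increasing) f(t) >= threshold else f(t) <= threshold
  iter <- 0L
  while (!crossed(upper)) {
    upper <- upper * 2
    iter <- iter + 1L
    if (iter > 200L) return(NA_real_)  # numerically unreachable
  }
  lo <- 0
  hi <- upper
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (crossed(mid)) hi <- mid else lo <- mid
  }
  hi
}
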