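#' Column-standardize a mean-response matrix
#'
#' Centers every channel to mean 0 and scales it to unit standard
#' deviation. The two sensor arrays live on incommensurate scales
#' (conductance ratios around 1-16 versus taste units), so the fused
#' decomposition operates on z-scores.
#'
#' @param m time x channel matrix with >= 2 rows.
#' @return the z-scored matrix (plain matrix, attributes dropped).
#' @export
standardizeMatrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need >= 2 rows", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("zero-variance channel: '",
         colnames(m)[sds == 0][1] %||% which(sds == 0)[1], "'",
         call. = FALSE)
  z <- scale(m, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Fuse sensor arrays by principal-component scores
#'
#' Principal components of the standardized time x channel matrix.
#' The number of retained components \code{k} is the smallest count
#' whose cumulative variance fraction reaches \code{minCumVariance}.
#' Each component's sign is oriented so that its score series
#' correlates negatively with storage time, matching the convention
#' that fused scores fall as spoilage progresses; this makes the
#' downstream negation reproducible. The composite score is filled in
#' by the variance-weight rule of [compositeScore()].
#'
#' @param z standardized time x channel matrix (see
#'   [standardizeMatrix()]); rownames, if numeric, are taken as the
#'   time grid.
#' @param minCumVariance fraction in (0, 1], default 0.90.
#' @param times optional explicit time grid (h).
#' @return a \linkS4class{FusionResult} (all components kept in
#'   \code{scores}/\code{loadings}; \code{k} marks the retained count).
#' @export
fusePCA <- function(z, minCumVariance = 0.90, times = NULL) {
  z <- as.matrix(z)
  if (length(minCumVariance) != 1L || !is.finite(minCumVariance) ||
      minCumVariance <= 0 || minCumVariance > 1)
    stop("invalid input: minCumVariance must lie in (0, 1]", call. = FALSE)
  if (is.null(times)) {
    times <- suppressWarnings(as.numeric(rownames(z)))
    if (any(is.na(times))) times <- seq_len(nrow(z))
  }
  pr <- prcomp(z, center = TRUE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x
  loadings <- pr$rotation
  ## orient: score series decreasing with time
  for (j in seq_len(ncol(scores))) {
    ct <- suppressWarnings(cor(scores[, j], times))
    if (is.finite(ct) && ct > 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  k <- which(cumsum(vf) >= minCumVariance - 1e-12)[1]
  if (is.na(k)) k <- length(vf)
  out <- new("FusionResult", scores = scores, varianceFractions = vf,
             loadings = loadings, k = as.integer(k),
             composite = rep(0, nrow(scores)), times = times)
  out@composite <- compositeScore(out)
  out
}

#' @rdname compositeScore
setMethod("compositeScore", signature("FusionResult", "missing"),
  function(object, weights) {
    k <- object@k
    as.numeric(object@scores[, seq_len(k), drop = FALSE] %*%
               object@varianceFractions[seq_len(k)])
  })

#' @rdname compositeScore
setMethod("compositeScore", signature("matrix", "numeric"),
  function(object, weights) {
    if (ncol(object) != length(weights))
      stop("one weight per component column is required", call. = FALSE)
    as.numeric(object %*% weights)
  })

#' Orient a composite score series for growth fitting
#'
#' Fused scores fall with storage time; the primary models are fitted
#' to the negated series, which rises like a growth curve. The applied
#' sign is recorded for traceability.
#'
#' @param composite numeric composite score series.
#' @return list with \code{series} (the negated scores) and
#'   \code{sign} (-1).
#' @export
orientForFitting <- function(composite) {
  .assertFiniteNumeric(composite, "composite")
  if (!length(composite)) stop("empty composite series", call. = FALSE)
  list(series = -composite, sign = -1)
}
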