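#' Accessors for kinetic parameters and fit results
#'
#' Small accessor family so downstream code never reaches into slots:
#' \code{n0}, \code{nMax}, \code{muMax} and \code{lagTime} read the four
#' kinetic parameters; \code{r2} and \code{rmse} read metrics;
#' \code{modelKind}, \code{fittedParams}, \code{trainMetrics} and
#' \code{testMetrics} read a \linkS4class{FitResult}.
#'
#' @param object the object to read from.
#' @return the requested scalar, object, or \code{NULL}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("n0", function(object) standardGeneric("n0"))
#' @rdname accessors
#' @export
setGeneric("nMax", function(object) standardGeneric("nMax"))
#' @rdname accessors
#' @export
setGeneric("muMax", function(object) standardGeneric("muMax"))
#' @rdname accessors
#' @export
setGeneric("lagTime", function(object) standardGeneric("lagTime"))
#' @rdname accessors
#' @export
setGeneric("r2", function(object) standardGeneric("r2"))
#' @rdname accessors
#' @export
setGeneric("rmse", function(object) standardGeneric("rmse"))
#' @rdname accessors
#' @export
setGeneric("modelKind", function(object) standardGeneric("modelKind"))
#' @rdname accessors
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))
#' @rdname accessors
#' @export
setGeneric("trainMetrics", function(object) standardGeneric("trainMetrics"))
#' @rdname accessors
#' @export
setGeneric("testMetrics", function(object) standardGeneric("testMetrics"))

#' @rdname accessors
setMethod("n0", "GrowthParams", function(object) object@n0)
#' @rdname accessors
setMethod("nMax", "GrowthParams", function(object) object@nMax)
#' @rdname accessors
setMethod("muMax", "GrowthParams", function(object) object@muMax)
#' @rdname accessors
setMethod("lagTime", "GrowthParams", function(object) object@lag)
#' @rdname accessors
setMethod("n0", "FitResult", function(object) object@params@n0)
#' @rdname accessors
setMethod("nMax", "FitResult", function(object) object@params@nMax)
#' @rdname accessors
setMethod("muMax", "FitResult", function(object) object@params@muMax)
#' @rdname accessors
setMethod("lagTime", "FitResult", function(object) object@params@lag)
#' @rdname accessors
setMethod("r2", "FitMetrics", function(object) object@r2)
#' @rdname accessors
setMethod("rmse", "FitMetrics", function(object) object@rmse)
#' @rdname accessors
setMethod("r2", "FitResult", function(object) object@train@r2)
#' @rdname accessors
setMethod("rmse", "FitResult", function(object) object@train@rmse)
#' @rdname accessors
setMethod("modelKind", "FitResult", function(object) object@kind)
#' @rdname accessors
setMethod("fittedParams", "FitResult", function(object) object@params)
#' @rdname accessors
setMethod("trainMetrics", "FitResult", function(object) object@train)
#' @rdname accessors
setMethod("testMetrics", "FitResult", function(object) object@test)

#' Count the distinct homogeneous-subset letters
#'
#' The discrimination count of a channel is the number of distinct
#' letters its multiple-range-test display uses: a channel that needs
#' many letters separates many storage times. Works on a
#' \linkS4class{LetterGrouping} or directly on a character vector of
#' letter strings (e.g. a published letter column such as
#' \code{c("a", "b", "bc", ...)}).
#'
#' @param grouping a \code{LetterGrouping} or character vector.
#' @return integer, number of distinct letters.
#' @examples
#' discriminationCount(c("a", "ab", "b", "c"))  # 3
#' @export
setGeneric("discriminationCount",
           function(grouping) standardGeneric("discriminationCount"))

#' Variance-weighted composite fusion score
#'
#' Collapses retained principal-component scores to one scalar per time
#' point: \code{score_t = sum_j fraction_j * score_{t,j}}, the weights
#' being the components' variance fractions taken as proportions.
#'
#' @param object a \linkS4class{FusionResult}, or a time x component
#'   score matrix.
#' @param weights variance fractions (proportions) when \code{object}
#'   is a matrix; ignored otherwise.
#' @return numeric, one composite score per time point.
#' @examples
#' compositeScore(rbind(c(5.50, 3.34, -0.51, -1.84)),
#'                c(0.6098, 0.1843, 0.0699, 0.0551))
#' @export
setGeneric("compositeScore",
           function(object, weights) standardGeneric("compositeScore"))
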