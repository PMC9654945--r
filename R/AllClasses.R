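#' @import methods
#' @importFrom stats cor median pf pt qtukey rnorm sd setNames var prcomp
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @rawNamespace exportMethods(show)
NULL

## ---------------------------------------------------------------------------
## Kinetic parameter container
## ---------------------------------------------------------------------------

#' Kinetic parameters of a primary growth model
#'
#' Holds the four parameters shared by the modified Gompertz, logistic,
#' Huang and Baranyi-Roberts primary models: the initial level \code{n0},
#' the asymptotic level \code{nMax}, the maximum specific rate
#' \code{muMax} (per hour) and the lag time \code{lag} (hours). Levels
#' are in whatever units the fitted series uses: Log CFU/mL for plate
#' counts, instrument units for sensor channels, unitless for fused
#' principal-component scores. Decreasing curves (declining sensor
#' responses) are expressed as \code{nMax < n0}; \code{muMax} stays
#' positive in either direction.
#'
#' @slot n0 numeric(1), level at the start of storage.
#' @slot nMax numeric(1), asymptotic level; must differ from \code{n0}.
#' @slot muMax numeric(1), maximum specific rate, > 0 (h^-1).
#' @slot lag numeric(1), lag time, >= 0 (h).
#' @aliases GrowthParams-class
#' @exportClass GrowthParams
setClass("GrowthParams",
  representation(n0 = "numeric", nMax = "numeric",
                 muMax = "numeric", lag = "numeric"))

setValidity("GrowthParams", function(object) {
  msg <- character()
  for (s in c("n0", "nMax", "muMax", "lag")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, paste0(s, " must be a finite scalar"))
  }
  if (!length(msg)) {
    if (object@muMax <= 0) msg <- c(msg, "muMax must be > 0")
    if (object@lag < 0) msg <- c(msg, "lag must be >= 0")
    if (object@nMax == object@n0) msg <- c(msg, "nMax must differ from n0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a \linkS4class{GrowthParams} object
#'
#' @param n0 initial level.
#' @param nMax asymptotic level (may be below \code{n0} for declining
#'   responses).
#' @param muMax maximum specific rate (h^-1), > 0.
#' @param lag lag time (h), >= 0.
#' @return a \code{GrowthParams} object.
#' @examples
#' growthParams(3.996, 5.337, 0.064, 97.85)
#' @export
growthParams <- function(n0, nMax, muMax, lag) {
  new("GrowthParams", n0 = as.numeric(n0), nMax = as.numeric(nMax),
      muMax = as.numeric(muMax), lag = as.numeric(lag))
}

setMethod("show", "GrowthParams", function(object) {
  cat(sprintf(
    "GrowthParams: n0 = %.4g, nMax = %.4g, muMax = %.4g /h, lag = %.4g h\n",
    object@n0, object@nMax, object@muMax, object@lag))
})

## ---------------------------------------------------------------------------
## CurveSeries
## ---------------------------------------------------------------------------

#' A sampled growth curve
#'
#' Pairs a strictly increasing, non-negative time grid (hours) with the
#' level observed or predicted at each time.
#'
#' @slot times numeric, hours, strictly increasing, >= 0.
#' @slot values numeric, same length as \code{times}.
#' @aliases CurveSeries-class
#' @exportClass CurveSeries
setClass("CurveSeries",
  representation(times = "numeric", values = "numeric"))

setValidity("CurveSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (any(!is.finite(object@times)))
    msg <- c(msg, "times must be finite")
  if (length(object@times) && any(object@times < 0))
    msg <- c(msg, "times must be >= 0")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a \linkS4class{CurveSeries}
#'
#' @param times hours, strictly increasing, >= 0.
#' @param values levels at those times.
#' @return a \code{CurveSeries} object.
#' @export
curveSeries <- function(times, values) {
  new("CurveSeries", times = as.numeric(times), values = as.numeric(values))
}

setMethod("show", "CurveSeries", function(object) {
  cat(sprintf("CurveSeries with %d points over [%g, %g] h\n",
              length(object@times),
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA))
})

#' @describeIn curveSeries number of sampled points.
#' @param x a \code{CurveSeries}.
#' @export
setMethod("length", "CurveSeries", function(x) length(x@times))

## ---------------------------------------------------------------------------
## Fit metrics / results / options
## ---------------------------------------------------------------------------

#' Goodness-of-fit metrics with degrees-of-freedom adjustment
#'
#' RMSE is computed as \code{sqrt(SSE / (n - p))} and the coefficient of
#' determination is adjusted by the factor \code{(n - 1) / (n - p)},
#' where \code{n} is the number of observations and \code{p} the number
#' of fitted parameters (4 for all primary models here).
#'
#' @slot r2 adjusted coefficient of determination (<= 1).
#' @slot rmse root mean square error, >= 0, in data units.
#' @slot n integer, number of observations.
#' @slot p integer, number of fitted parameters, < n.
#' @aliases FitMetrics-class
#' @exportClass FitMetrics
setClass("FitMetrics",
  representation(r2 = "numeric", rmse = "numeric",
                 n = "integer", p = "integer"))

setValidity("FitMetrics", function(object) {
  msg <- character()
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (object@n <= object@p) msg <- c(msg, "n must exceed p")
  if (object@r2 > 1 + 1e-12) msg <- c(msg, "r2 must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FitMetrics", function(object) {
  cat(sprintf("FitMetrics: adj R2 = %.4f, RMSE = %.4f (n = %d, p = %d)\n",
              object@r2, object@rmse, object@n, object@p))
})

setClassUnion("FitMetricsOrNULL", c("FitMetrics", "NULL"))

#' Options controlling nonlinear least-squares fitting
#'
#' @slot nRestarts integer >= 1, number of optimizer starts (one
#'   data-driven heuristic start plus Latin-hypercube starts).
#' @slot seed integer seed controlling the Latin-hypercube draws, so a
#'   fit is reproducible bit-for-bit.
#' @slot bounds named list with elements \code{lower}/\code{upper}
#'   (each length-4 numeric: n0, nMax, muMax, lag), or empty to derive
#'   bounds from the data.
#' @slot tolerance relative convergence tolerance on the residual sum
#'   of squares.
#' @aliases FitOptions-class
#' @exportClass FitOptions
setClass("FitOptions",
  representation(nRestarts = "integer", seed = "integer",
                 bounds = "list", tolerance = "numeric"))

setValidity("FitOptions", function(object) {
  if (object@nRestarts < 1L) "nRestarts must be >= 1" else TRUE
})

#' Construct fitting options
#'
#' @param nRestarts number of optimizer starts (default 32).
#' @param seed RNG seed for the Latin-hypercube restarts (default 1).
#' @param bounds optional named list with \code{lower} and \code{upper}
#'   length-4 vectors (n0, nMax, muMax, lag).
#' @param tolerance relative SSE convergence tolerance (default 1e-12).
#' @return a \code{FitOptions} object.
#' @export
fitOptions <- function(nRestarts = 32L, seed = 1L, bounds = list(),
                       tolerance = 1e-12) {
  new("FitOptions", nRestarts = as.integer(nRestarts),
      seed = as.integer(seed), bounds = bounds,
      tolerance = as.numeric(tolerance))
}

#' Result of fitting one primary growth model
#'
#' @slot kind model kind, one of \code{modelKinds()}.
#' @slot params fitted \linkS4class{GrowthParams}.
#' @slot train training \linkS4class{FitMetrics}.
#' @slot test testing metrics, or \code{NULL} when no held-out set was
#'   evaluated.
#' @slot r Pearson correlation between the fitted curve and a reference
#'   series; length 0 when no reference was supplied.
#' @slot sse residual sum of squares of the training fit.
#' @slot converged logical, whether any restart converged.
#' @slot restartsUsed integer, number of optimizer starts attempted.
#' @aliases FitResult-class
#' @exportClass FitResult
setClass("FitResult",
  representation(kind = "character", params = "GrowthParams",
                 train = "FitMetrics", test = "FitMetricsOrNULL",
                 r = "numeric", sse = "numeric",
                 converged = "logical", restartsUsed = "integer"))

setValidity("FitResult", function(object) {
  if (length(object@r) > 1L) return("r must have length 0 or 1")
  if (length(object@r) == 1L && (object@r < -1 - 1e-12 || object@r > 1 + 1e-12))
    return("r must lie in [-1, 1]")
  TRUE
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]%s\n", object@kind,
              if (object@converged) "" else " (NOT converged)"))
  show(object@params)
  cat("  train: "); show(object@train)
  if (!is.null(object@test)) { cat("  test:  "); show(object@test) }
  if (length(object@r))
    cat(sprintf("  r vs reference = %.4f\n", object@r))
})

## ---------------------------------------------------------------------------
## Selection-stage containers
## ---------------------------------------------------------------------------

#' One-way ANOVA reconstructed from summary statistics
#'
#' @slot fStat F statistic, >= 0 (may be \code{Inf} when all
#'   within-group standard deviations are zero but means differ).
#' @slot dfBetween integer, groups - 1.
#' @slot dfWithin integer, sum of (n_i - 1).
#' @slot pValue upper-tail p-value from the F distribution.
#' @slot mse pooled within-group mean square (response units squared).
#' @aliases AnovaResult-class
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(fStat = "numeric", dfBetween = "integer",
                 dfWithin = "integer", pValue = "numeric", mse = "numeric"))

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("AnovaResult: F(%d, %d) = %.4g, p = %.3g, MSE = %.4g\n",
              object@dfBetween, object@dfWithin, object@fStat,
              object@pValue, object@mse))
})

#' Duncan multiple-range-test letter display
#'
#' Homogeneous-subset letters per time point for one channel: two time
#' points share a letter exactly when their means were not separated at
#' the stated significance level. The letter \code{a} is attached to the
#' largest mean, following the usual descending-means display.
#'
#' @slot time numeric, time points (h), in input order.
#' @slot mean numeric, group means in input order.
#' @slot letters character, letter string per time point.
#' @slot alpha significance level used.
#' @slot order integer, permutation sorting means in decreasing order.
#' @aliases LetterGrouping-class
#' @exportClass LetterGrouping
setClass("LetterGrouping",
  representation(time = "numeric", mean = "numeric", letters = "character",
                 alpha = "numeric", order = "integer"))

setValidity("LetterGrouping", function(object) {
  if (any(!nzchar(object@letters)))
    return("every time point needs at least one letter")
  TRUE
})

setMethod("show", "LetterGrouping", function(object) {
  cat(sprintf("LetterGrouping (alpha = %g): %d groups, %d distinct letters\n",
              object@alpha, length(object@time),
              length(unique(unlist(strsplit(object@letters, "(?<=.)(?=[a-z])",
                                            perl = TRUE))))))
  print(data.frame(time_h = object@time, mean = object@mean,
                   letters = object@letters))
})

#' Pearson correlation matrix with significance stars
#'
#' @slot r symmetric correlation matrix with unit diagonal.
#' @slot p two-sided p-values (diagonal \code{NA}).
#' @slot stars character matrix: \code{""}, \code{"*"} (p < 0.05) or
#'   \code{"**"} (p < 0.01).
#' @slot n number of paired observations.
#' @aliases CorrelationTable-class
#' @exportClass CorrelationTable
setClass("CorrelationTable",
  representation(r = "matrix", p = "matrix", stars = "matrix", n = "integer"))

setValidity("CorrelationTable", function(object) {
  if (max(abs(object@r - t(object@r))) > 1e-12) return("r must be symmetric")
  if (max(abs(diag(object@r) - 1)) > 1e-12) return("diagonal must be 1")
  TRUE
})

setMethod("show", "CorrelationTable", function(object) {
  cat(sprintf("CorrelationTable over %d series (n = %d)\n",
              ncol(object@r), object@n))
  disp <- matrix(paste0(formatC(object@r, digits = 3, format = "f"),
                        ifelse(object@stars == "", "", " "), object@stars),
                 nrow(object@r), dimnames = dimnames(object@r))
  print(disp, quote = FALSE)
})

## ---------------------------------------------------------------------------
## Fusion container
## ---------------------------------------------------------------------------

#' Principal-component fusion of the two sensor arrays
#'
#' @slot scores time x component score matrix (all components).
#' @slot varianceFractions per-component variance fractions,
#'   non-increasing, summing to 1 over all components.
#' @slot loadings channel x component orthonormal loading matrix.
#' @slot k integer, number of retained components.
#' @slot composite per-time variance-weighted composite score over the
#'   retained components.
#' @slot times numeric, the time grid (h).
#' @aliases FusionResult-class
#' @exportClass FusionResult
setClass("FusionResult",
  representation(scores = "matrix", varianceFractions = "numeric",
                 loadings = "matrix", k = "integer",
                 composite = "numeric", times = "numeric"))

setValidity("FusionResult", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@varianceFractions), strictly = FALSE))
    msg <- c(msg, "variance fractions must be non-increasing")
  if (sum(object@varianceFractions[seq_len(object@k)]) > 1 + 1e-8)
    msg <- c(msg, "retained variance fractions must sum to <= 1")
  if (length(object@composite) != nrow(object@scores))
    msg <- c(msg, "composite length must equal number of times")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FusionResult", function(object) {
  cat(sprintf(
    "FusionResult: %d times, %d channels, k = %d retained (%.2f%% variance)\n",
    nrow(object@scores), nrow(object@loadings), object@k,
    100 * sum(object@varianceFractions[seq_len(object@k)])))
})

## ---------------------------------------------------------------------------
## Replicate panel (SummarizedExperiment)
## ---------------------------------------------------------------------------

#' Replicate-level sensor panel
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' \code{"response"} holds channels in rows and one column per
#' (time, replicate) sample, with \code{time_h} and \code{replicate} in
#' the column data. This is the container every screening and fitting
#' stage consumes.
#'
#' @aliases ReplicatePanel-class
#' @exportClass ReplicatePanel
setClass("ReplicatePanel", contains = "SummarizedExperiment")

setValidity("ReplicatePanel", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time_h", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain time_h and replicate")
  if (!"response" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'response' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a \linkS4class{ReplicatePanel}
#'
#' @param response numeric matrix, channels x samples.
#' @param time_h numeric, storage time (h) per sample column.
#' @param replicate integer replicate index per sample column.
#' @return a \code{ReplicatePanel}.
#' @examples
#' m <- matrix(rnorm(12), 2, 6, dimnames = list(c("S1", "S2"), NULL))
#' replicatePanel(m, time_h = rep(c(0, 12), each = 3), replicate = rep(1:3, 2))
#' @export
replicatePanel <- function(response, time_h, replicate) {
  response <- as.matrix(response)
  if (is.null(rownames(response)))
    stop("response matrix needs channel rownames", call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(response = response),
    colData = S4Vectors::DataFrame(time_h = as.numeric(time_h),
                                   replicate = as.integer(replicate)))
  new("ReplicatePanel", se)
}

#' @describeIn replicatePanel distinct storage times, sorted.
#' @param panel a \code{ReplicatePanel}.
#' @export
panelTimes <- function(panel) {
  sort(unique(SummarizedExperiment::colData(panel)$time_h))
}

#' @describeIn replicatePanel channel names.
#' @export
panelChannels <- function(panel) rownames(panel)

## ---------------------------------------------------------------------------
## Study design / pipeline containers
## ---------------------------------------------------------------------------

#' Design constants of the cold-storage study
#'
#' Defaults mirror the emulated study: juice sampled every 12 h for
#' 7 days (15 time points), 20 replicate samples per time of which the
#' first 15 form the training split, 10 E-nose channels and 9 E-tongue
#' taste channels.
#'
#' @slot times sampling times (h).
#' @slot replicates replicates per time point.
#' @slot trainReplicates number of replicates in the training split.
#' @slot enoseChannels E-nose channel names.
#' @slot tasteChannels E-tongue channel names.
#' @aliases StudyDesign-class
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(times = "numeric", replicates = "integer",
                 trainReplicates = "integer", enoseChannels = "character",
                 tasteChannels = "character"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@times) < 5L) msg <- c(msg, "need >= 5 sampling times")
  if (object@replicates < 2L) msg <- c(msg, "need >= 2 replicates")
  if (object@trainReplicates < 1L ||
      object@trainReplicates >= object@replicates)
    msg <- c(msg, "train split must leave at least one test replicate")
  if (length(msg)) msg else TRUE
})

#' Construct a \linkS4class{StudyDesign}
#'
#' @param times sampling times in hours.
#' @param replicates replicate samples per time point.
#' @param trainReplicates replicates assigned to the training split;
#'   the remainder form the test split.
#' @param enoseChannels,tasteChannels channel names of the two arrays.
#' @return a \code{StudyDesign}.
#' @export
studyDesign <- function(times = seq(0, 168, by = 12), replicates = 20L,
                        trainReplicates = 15L,
                        enoseChannels = paste0("S", 1:10),
                        tasteChannels = c("sourness", "bitterness",
                                          "astringency", "aftertaste_b",
                                          "aftertaste_a", "umami", "richness",
                                          "saltiness", "sweetness")) {
  new("StudyDesign", times = as.numeric(times),
      replicates = as.integer(replicates),
      trainReplicates = as.integer(trainReplicates),
      enoseChannels = enoseChannels, tasteChannels = tasteChannels)
}

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "StudyDesign: %d times over [%g, %g] h, %d replicates (%d train / %d test),\n  %d E-nose + %d taste channels\n",
    length(object@times), min(object@times), max(object@times),
    object@replicates, object@trainReplicates,
    object@replicates - object@trainReplicates,
    length(object@enoseChannels), length(object@tasteChannels)))
})

#' Pipeline configuration
#'
#' @slot input \code{"fixture:<seed>"} to simulate, or a path to a tidy
#'   measurement CSV (columns \code{time_h, replicate, channel, value}).
#' @slot mode \code{"full"} for the whole screen-fit-fuse pipeline, or
#'   \code{"fused-fit"} to fit the four models to a packaged or supplied
#'   component-score table only.
#' @slot alpha significance level for ANOVA/Duncan screening.
#' @slot minCumVariance cumulative-variance threshold for retaining
#'   fused principal components.
#' @slot fitOptions a \linkS4class{FitOptions}.
#' @slot threshold shelf-life threshold in Log CFU/mL.
#' @slot outputDir directory for rendered reports (may be empty).
#' @slot enoseChannels,tasteChannels channel grouping used for
#'   selection.
#' @aliases PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(input = "character", mode = "character", alpha = "numeric",
                 minCumVariance = "numeric", fitOptions = "FitOptions",
                 threshold = "numeric", outputDir = "character",
                 enoseChannels = "character", tasteChannels = "character"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 0.5)
    msg <- c(msg, "alpha must lie in (0, 0.5)")
  if (!is.finite(object@threshold)) msg <- c(msg, "threshold must be finite")
  if (!object@mode %in% c("full", "fused-fit"))
    msg <- c(msg, "mode must be 'full' or 'fused-fit'")
  if (length(msg)) msg else TRUE
})

#' Construct a \linkS4class{PipelineConfig}
#'
#' @param input \code{"fixture:<seed>"} or a measurement CSV path; for
#'   \code{mode = "fused-fit"}, a component-score CSV path or \code{""}
#'   for the packaged score table.
#' @param mode \code{"full"} or \code{"fused-fit"}.
#' @param alpha significance level for the screening stage.
#' @param minCumVariance retained cumulative variance for fusion.
#' @param fitOptions a \linkS4class{FitOptions}.
#' @param threshold shelf-life threshold (Log CFU/mL).
#' @param outputDir where \code{renderReport} writes files.
#' @param enoseChannels,tasteChannels channel grouping.
#' @return a \code{PipelineConfig}.
#' @export
pipelineConfig <- function(input = "fixture:1", mode = "full", alpha = 0.05,
                           minCumVariance = 0.90, fitOptions = GrowthSense::fitOptions(),
                           threshold = 5, outputDir = character(),
                           enoseChannels = paste0("S", 1:10),
                           tasteChannels = c("sourness", "bitterness",
                                             "astringency", "aftertaste_b",
                                             "aftertaste_a", "umami",
                                             "richness", "saltiness",
                                             "sweetness")) {
  new("PipelineConfig", input = input, mode = mode, alpha = alpha,
      minCumVariance = minCumVariance, fitOptions = fitOptions,
      threshold = threshold, outputDir = as.character(outputDir),
      enoseChannels = enoseChannels, tasteChannels = tasteChannels)
}

#' End-to-end study report
#'
#' @slot selection evidence from the screening stage (discrimination
#'   counts, correlations, loadings, selected channels).
#' @slot fits named list (one element per data source) of named lists of
#'   \linkS4class{FitResult} objects or failure records.
#' @slot shelfLife named numeric, estimated threshold-crossing time per
#'   source (\code{NA} when the threshold is not reachable or not in the
#'   source's units).
#' @slot fusion the \linkS4class{FusionResult}, or \code{NULL}.
#' @slot provenance seed, configuration echo and hash, timestamp.
#' @aliases StudyReport-class
#' @exportClass StudyReport
setClass("StudyReport",
  representation(selection = "list", fits = "list", shelfLife = "numeric",
                 fusion = "ANY", provenance = "list"))

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n")
  if (length(object@selection)) {
    cat(sprintf("  selected E-nose channel: %s\n",
                object@selection$enoseChannel %||% "<none>"))
    cat(sprintf("  selected taste channel:  %s\n",
                object@selection$tasteChannel %||% "<none>"))
  }
  for (src in names(object@fits)) {
    ok <- vapply(object@fits[[src]], function(f) is(f, "FitResult"), TRUE)
    cat(sprintf("  source %-12s %d/%d model fits\n", src, sum(ok), length(ok)))
  }
  sl <- object@shelfLife[is.finite(object@shelfLife)]
  if (length(sl))
    cat(sprintf("  shelf life [%s]: %.1f h\n", names(sl)[1], sl[1]))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
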