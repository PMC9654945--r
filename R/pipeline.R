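## End-to-end orchestration: summarize -> screen (ANOVA / Duncan /
## Pearson / loadings) -> fit the four primary models per data source
## (plate counts, selected E-nose channel, selected taste channel,
## fused composite score) -> shelf life -> report.

.configAsList <- function(config) {
  list(input = config@input, mode = config@mode, alpha = config@alpha,
       minCumVariance = config@minCumVariance,
       threshold = config@threshold,
       fitOptions = list(nRestarts = config@fitOptions@nRestarts,
                         seed = config@fitOptions@seed,
                         tolerance = config@fitOptions@tolerance),
       enoseChannels = config@enoseChannels,
       tasteChannels = config@tasteChannels)
}

.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(.configAsList(config)), tf)
  unname(tools::md5sum(tf))
}

.resolvePanel <- function(config) {
  if (grepl("^fixture:", config@input)) {
    seed <- as.integer(sub("^fixture:", "", config@input))
    if (is.na(seed)) stop("bad fixture reference: ", config@input,
                          call. = FALSE)
    makeFixture(seed)
  } else {
    panel <- loadPanel(config@input)
    design <- studyDesign(times = panelTimes(panel),
                          replicates = max(
                            SummarizedExperiment::colData(panel)$replicate),
                          enoseChannels = intersect(config@enoseChannels,
                                                    panelChannels(panel)),
                          tasteChannels = intersect(config@tasteChannels,
                                                    panelChannels(panel)))
    list(panel = panel, design = design,
         trainReplicates = seq_len(design@trainReplicates),
         testReplicates = seq.int(design@trainReplicates + 1L,
                                  design@replicates))
  }
}

.fitSourceAll <- function(series, options, reference) {
  lapply(fitAll(series, options, reference), identity)
}

.fitSourceValidated <- function(panel, trainIdx, testIdx, channel, options,
                                reference) {
  trainPanel <- .splitPanel(panel, trainIdx)
  testPanel <- .splitPanel(panel, testIdx)
  fits <- lapply(modelKinds(), function(k) {
    tryCatch(
      fitWithValidation(trainPanel, testPanel, channel, k, options,
                        reference),
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

.bestFit <- function(fits) {
  ok <- Filter(function(f) is(f, "FitResult"), fits)
  if (length(ok)) ok[[1]] else NULL
}

#' Run the full study pipeline
#'
#' Executes, deterministically for a given configuration, the complete
#' analysis: replicate summaries; E-nose screening by ANOVA + Duncan
#' discrimination counts, Pearson correlation with the plate-count log
#' series and PC1 loadings; taste screening by correlation; fits of the
#' four primary models to plate-count means, to the selected channel of
#' each array (with train/test validation), and to the negated fused
#' composite score; and a shelf-life estimate from the best plate-count
#' fit. With \code{mode = "fused-fit"} only the composite-score fitting
#' stage runs, against the packaged (or a user-supplied) score table.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return a \linkS4class{StudyReport}.
#' @examples
#' \donttest{
#' rep <- runPipeline(pipelineConfig("fixture:1",
#'                                   fitOptions = fitOptions(nRestarts = 8)))
#' rep
#' }
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  opt <- config@fitOptions
  prov <- list(seed = opt@seed, config = .configAsList(config),
               configHash = .configHash(config),
               generated = format(Sys.time(), tz = "UTC",
                                  "%Y-%m-%dT%H:%M:%SZ"))

  if (config@mode == "fused-fit") {
    tab <- if (nzchar(config@input)) {
      utils::read.csv(config@input, stringsAsFactors = FALSE)
    } else pcScoresTable()$scores
    if (!"score" %in% names(tab))
      stop("schema error: missing column 'score'", call. = FALSE)
    oriented <- orientForFitting(tab$score)
    fits <- fitAll(curveSeries(tab$time_h, oriented$series), opt)
    return(new("StudyReport",
               selection = list(),
               fits = list(fused = fits),
               shelfLife = c(fused = NA_real_),
               fusion = NULL, provenance = prov))
  }

  fx <- .resolvePanel(config)
  panel <- fx$panel
  design <- fx$design
  enoseCh <- intersect(design@enoseChannels, panelChannels(panel))
  tasteCh <- intersect(design@tasteChannels, panelChannels(panel))
  if (!"log_cfu" %in% panelChannels(panel))
    stop("missing channel: 'log_cfu' (plate counts) is required",
         call. = FALSE)
  if (!length(enoseCh) || !length(tasteCh))
    stop("missing channels: need at least one E-nose and one taste channel",
         call. = FALSE)

  summaries <- summarizePanel(panel)
  countsMeans <- .panelChannelMeans(panel, "log_cfu")

  ## E-nose screening
  duncan <- lapply(setNames(enoseCh, enoseCh), function(ch) {
    g <- summaries[summaries$channel == ch, ]
    duncanLetters(g, anovaFromSummary(g), config@alpha)
  })
  counts <- vapply(duncan, discriminationCount, 0L)
  meanMat <- .panelMeanMatrix(panel, c(enoseCh, tasteCh, "log_cfu"))
  corTab <- pearsonWithStars(meanMat)
  rWithCounts <- corTab@r[, "log_cfu"]
  loadings <- enoseLoadings(meanMat[, enoseCh, drop = FALSE])
  ranking <- rankSensors(counts, rWithCounts[enoseCh],
                         setNames(loadings$loadings[enoseCh, 1], enoseCh))
  enoseSel <- ranking[1]
  tasteSel <- tasteCh[which.max(abs(rWithCounts[tasteCh]))]

  ## fusion of all sensor channels (per-time means)
  z <- standardizeMatrix(meanMat[, c(enoseCh, tasteCh), drop = FALSE])
  rownames(z) <- rownames(meanMat)
  fusion <- fusePCA(z, config@minCumVariance, times = countsMeans$times)
  oriented <- orientForFitting(fusion@composite)

  ## model fits per source
  ref <- countsMeans$means
  fits <- list(
    counts = fitAll(curveSeries(countsMeans$times, countsMeans$means),
                    opt, reference = ref),
    enose = .fitSourceValidated(panel, fx$trainReplicates,
                                fx$testReplicates, enoseSel, opt, ref),
    taste = .fitSourceValidated(panel, fx$trainReplicates,
                                fx$testReplicates, tasteSel, opt, ref),
    fused = fitAll(curveSeries(countsMeans$times, oriented$series),
                   opt, reference = ref))

  ## shelf life: meaningful on the Log CFU/mL scale only
  shelf <- c(counts = NA_real_, enose = NA_real_, taste = NA_real_,
             fused = NA_real_)
  bestCounts <- .bestFit(fits$counts)
  if (!is.null(bestCounts))
    shelf["counts"] <- shelfLifeTime(bestCounts@kind, bestCounts@params,
                                     config@threshold)

  new("StudyReport",
      selection = list(
        enoseChannel = enoseSel, tasteChannel = tasteSel,
        ranking = ranking, discriminationCounts = counts,
        rWithCounts = rWithCounts, duncan = duncan,
        loadings = loadings, correlations = corTab),
      fits = fits, shelfLife = shelf, fusion = fusion, provenance = prov)
}

## ---------------------------------------------------------------------------
## Report rendering
## ---------------------------------------------------------------------------

.metricsAsList <- function(m) {
  if (is.null(m)) return(NULL)
  list(r2 = m@r2, rmse = m@rmse, n = m@n, p = m@p)
}

.fitAsList <- function(f) {
  if (!is(f, "FitResult"))
    return(list(kind = f$kind, error = f$error))
  list(kind = f@kind,
       params = list(n0 = f@params@n0, nmax = f@params@nMax,
                     mu_max = f@params@muMax, lag = f@params@lag),
       train = .metricsAsList(f@train),
       test = .metricsAsList(f@test),
       r = if (length(f@r)) f@r else NULL,
       sse = f@sse, converged = f@converged,
       restarts_used = f@restartsUsed)
}

.reportAsList <- function(report) {
  sel <- report@selection
  list(
    selection = if (length(sel)) list(
      enose_channel = sel$enoseChannel,
      taste_channel = sel$tasteChannel,
      ranking = sel$ranking,
      discrimination_counts = as.list(sel$discriminationCounts),
      r_with_counts = as.list(sel$rWithCounts)) else NULL,
    fits = lapply(report@fits, function(src) lapply(src, .fitAsList)),
    shelf_life_h = as.list(report@shelfLife),
    fusion = if (!is.null(report@fusion)) list(
      k = report@fusion@k,
      variance_fractions = report@fusion@varianceFractions,
      composite = report@fusion@composite) else NULL,
    provenance = report@provenance)
}

.modelTableRow <- function(f) {
  if (!is(f, "FitResult"))
    return(data.frame(model = f$kind, lambda_h = NA, mu_max_per_h = NA,
                      n0 = NA, nmax = NA, r2_train = NA, rmse_train = NA,
                      r2_test = NA, rmse_test = NA, r = NA))
  data.frame(model = f@kind, lambda_h = f@params@lag,
             mu_max_per_h = f@params@muMax, n0 = f@params@n0,
             nmax = f@params@nMax, r2_train = f@train@r2,
             rmse_train = f@train@rmse,
             r2_test = if (is.null(f@test)) NA else f@test@r2,
             rmse_test = if (is.null(f@test)) NA else f@test@rmse,
             r = if (length(f@r)) f@r else NA)
}

#' Render a study report to files
#'
#' JSON is the canonical machine-readable output; one CSV model table
#' per data source mirrors the conventional reporting layout (model,
#' lag, rate, levels, train/test metrics, reference correlation); the
#' markdown summary is for humans and includes the shelf-life line
#' whenever the threshold was crossed.
#'
#' @param report a \linkS4class{StudyReport}.
#' @param dir output directory (created if needed).
#' @param formats subset of \code{c("json", "csv", "markdown")}.
#' @return invisibly, the paths written.
#' @export
renderReport <- function(report, dir,
                         formats = c("json", "csv", "markdown")) {
  stopifnot(is(report, "StudyReport"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(.reportAsList(report), p, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("csv" %in% formats) {
    for (src in names(report@fits)) {
      p <- file.path(dir, paste0("fits_", src, ".csv"))
      tab <- do.call(rbind, lapply(report@fits[[src]], .modelTableRow))
      utils::write.csv(tab, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("markdown" %in% formats) {
    p <- file.path(dir, "report.md")
    lines <- c("# Growth-model study report", "")
    if (length(report@selection)) {
      lines <- c(lines,
                 sprintf("Selected E-nose channel: **%s**",
                         report@selection$enoseChannel),
                 sprintf("Selected taste channel: **%s**",
                         report@selection$tasteChannel), "")
    }
    for (src in names(report@fits)) {
      lines <- c(lines, sprintf("## Source: %s", src), "")
      for (f in report@fits[[src]]) {
        lines <- c(lines, if (is(f, "FitResult"))
          sprintf("- %s: adj R2 = %.3f, RMSE = %.3f%s", f@kind,
                  f@train@r2, f@train@rmse,
                  if (length(f@r)) sprintf(", r = %.3f", f@r) else "")
          else sprintf("- %s: FAILED (%s)", f$kind, f$error))
      }
      lines <- c(lines, "")
    }
    sl <- report@shelfLife[is.finite(report@shelfLife)]
    if (length(sl))
      lines <- c(lines, sprintf(
        "Shelf life (threshold crossing, source %s): %.1f h",
        names(sl)[1], sl[1]))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
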