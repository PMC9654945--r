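#' Read a tidy measurement CSV into a \linkS4class{ReplicatePanel}
#'
#' The exchange format is a comma-separated, UTF-8, "."-decimal table
#' with header \code{time_h, replicate, channel, value}, one row per
#' measurement. Missing columns, non-numeric values and duplicate
#' (time, replicate, channel) triples are rejected with the offending
#' column or triple named.
#'
#' @param path CSV file path.
#' @return a \linkS4class{ReplicatePanel}.
#' @seealso [writePanel()]
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_h", "replicate", "channel", "value")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("time_h", "replicate", "value")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop("schema error: non-numeric entries in column '", col, "'",
           call. = FALSE)
    df[[col]] <- v
  }
  key <- paste(df$time_h, df$replicate, df$channel, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop("duplicate measurement for (time_h = ", d[1], ", replicate = ",
         d[2], ", channel = ", d[3], ")", call. = FALSE)
  }
  channels <- unique(df$channel)
  samples <- unique(df[c("time_h", "replicate")])
  samples <- samples[order(samples$time_h, samples$replicate), , drop = FALSE]
  m <- matrix(NA_real_, length(channels), nrow(samples),
              dimnames = list(channels, NULL))
  col <- match(paste(df$time_h, df$replicate),
               paste(samples$time_h, samples$replicate))
  m[cbind(match(df$channel, channels), col)] <- df$value
  replicatePanel(m, samples$time_h, samples$replicate)
}

#' Write a \linkS4class{ReplicatePanel} as a tidy measurement CSV
#'
#' @param panel a \code{ReplicatePanel}.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "ReplicatePanel"))
  m <- SummarizedExperiment::assay(panel, "response")
  cd <- SummarizedExperiment::colData(panel)
  df <- data.frame(
    time_h = rep(cd$time_h, each = nrow(m)),
    replicate = rep(cd$replicate, each = nrow(m)),
    channel = rep(rownames(m), times = ncol(m)),
    value = as.vector(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-channel, per-time summary statistics of a replicate panel
#'
#' Reduces the replicate dimension to mean, sample standard deviation
#' (n - 1 denominator) and replicate count for every channel x time
#' cell — the summary representation all screening stages (ANOVA,
#' Duncan, Pearson) consume, and the format in which sensor tables are
#' published.
#'
#' @param panel a \linkS4class{ReplicatePanel}.
#' @return data.frame with columns
#'   \code{channel, time_h, mean, sd, n}, ordered by channel then time.
#' @export
summarizePanel <- function(panel) {
  stopifnot(is(panel, "ReplicatePanel"))
  m <- SummarizedExperiment::assay(panel, "response")
  if (!ncol(m)) stop("panel is empty", call. = FALSE)
  tt <- SummarizedExperiment::colData(panel)$time_h
  times <- sort(unique(tt))
  out <- do.call(rbind, lapply(rownames(m), function(ch) {
    vals <- split(m[ch, ], tt)
    n <- vapply(vals, length, 0L)
    if (any(n < 2L))
      stop("insufficient replicates for channel '", ch, "' at time ",
           names(vals)[which(n < 2L)[1]], " h (n < 2)", call. = FALSE)
    data.frame(channel = ch, time_h = as.numeric(names(vals)),
               mean = vapply(vals, mean, 0),
               sd = vapply(vals, sd, 0),
               n = n, row.names = NULL)
  }))
  out[order(match(out$channel, rownames(m)), out$time_h), , drop = FALSE]
}

## time x channel matrix of per-time means, channels in panel order
.panelMeanMatrix <- function(panel, channels = panelChannels(panel)) {
  s <- summarizePanel(panel[channels, ])
  times <- sort(unique(s$time_h))
  m <- matrix(NA_real_, length(times), length(channels),
              dimnames = list(as.character(times), channels))
  m[cbind(match(s$time_h, times), match(s$channel, channels))] <- s$mean
  m
}

## split a panel by replicate indices
.splitPanel <- function(panel, replicates) {
  panel[, SummarizedExperiment::colData(panel)$replicate %in% replicates]
}
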