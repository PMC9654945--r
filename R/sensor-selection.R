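#' One-way ANOVA reconstructed exactly from summary statistics
#'
#' When only per-group means, standard deviations and sizes are
#' available (the form in which sensor panels are published), the
#' one-way ANOVA decomposition is still exact:
#' \code{SS_between = sum n_i (m_i - grand)^2} and
#' \code{SS_within = sum (n_i - 1) sd_i^2}. The result is identical to
#' running \code{aov} on the raw replicates.
#'
#' @param groups data.frame for one channel with columns
#'   \code{mean, sd, n} (one row per time point / group).
#' @return an \linkS4class{AnovaResult}. When every within-group sd is
#'   zero but means differ, the F statistic is \code{Inf} with p = 0 —
#'   a degenerate but unambiguous separation signal.
#' @examples
#' anovaFromSummary(data.frame(mean = c(0, 1), sd = 1, n = 2))
#' @export
anovaFromSummary <- function(groups) {
  stopifnot(is.data.frame(groups), all(c("mean", "sd", "n") %in% names(groups)))
  k <- nrow(groups)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(groups$n < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (any(groups$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  n <- groups$n
  m <- groups$mean
  grand <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * groups$sd^2)
  dfb <- k - 1L
  dfw <- as.integer(sum(n - 1L))
  msb <- ssb / dfb
  msw <- ssw / dfw
  f <- if (msw == 0) { if (ssb == 0) 0 else Inf } else msb / msw
  p <- if (is.infinite(f)) 0 else pf(f, dfb, dfw, lower.tail = FALSE)
  new("AnovaResult", fStat = f, dfBetween = dfb, dfWithin = dfw,
      pValue = p, mse = msw)
}

## Duncan critical range for a stretch of `span` adjacent ordered means:
## studentized-range quantile at the Duncan protection level
## (1 - alpha)^(span - 1), scaled by sqrt(MSE / n_h) with n_h the
## harmonic mean group size.
.duncanRange <- function(span, alpha, dfWithin, mse, nHarmonic) {
  qtukey((1 - alpha)^(span - 1), span, dfWithin) * sqrt(mse / nHarmonic)
}

#' Duncan's multiple range test with homogeneous-subset letters
#'
#' Sorts the group means in decreasing order and compares every ordered
#' pair against the critical range for the stretch it spans; letters are
#' then assigned by the standard sweep so that any two groups inside a
#' non-significant stretch share a letter. Unequal group sizes enter
#' through the harmonic mean.
#'
#' @param groups data.frame for one channel with columns
#'   \code{time_h, mean, sd, n}.
#' @param anova the matching \linkS4class{AnovaResult} (supplies MSE and
#'   within-group degrees of freedom); defaults to recomputing it from
#'   \code{groups}.
#' @param alpha significance level in (0, 0.5), default 0.05.
#' @return a \linkS4class{LetterGrouping} in the input row order.
#' @export
duncanLetters <- function(groups, anova = anovaFromSummary(groups),
                          alpha = 0.05) {
  stopifnot(is.data.frame(groups),
            all(c("time_h", "mean", "n") %in% names(groups)),
            is(anova, "AnovaResult"))
  if (alpha <= 0 || alpha >= 0.5)
    stop("alpha must lie in (0, 0.5)", call. = FALSE)
  if (anova@dfWithin < 1L)
    stop("dfWithin must be >= 1", call. = FALSE)
  k <- nrow(groups)
  ord <- order(groups$mean, decreasing = TRUE)
  m <- groups$mean[ord]
  nh <- k / sum(1 / groups$n)
  ranges <- vapply(2:max(k, 2L), .duncanRange, 0, alpha = alpha,
                   dfWithin = anova@dfWithin, mse = anova@mse,
                   nHarmonic = nh)
  separated <- function(i, j)  # i < j on the sorted scale
    (m[i] - m[j]) >= ranges[j - i]

  ## maximal non-significant stretches of the ordered means
  stretches <- vector("list", k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !separated(i, j + 1L)) j <- j + 1L
    stretches[[i]] <- c(i, j)
  }
  stretches <- unique(stretches)
  maximal <- vapply(seq_along(stretches), function(a) {
    sa <- stretches[[a]]
    !any(vapply(stretches, function(sb)
      sb[1] <= sa[1] && sa[2] <= sb[2] && !all(sb == sa), TRUE))
  }, TRUE)
  stretches <- stretches[maximal]
  stretches <- stretches[order(vapply(stretches, `[`, 0, 1))]

  lab <- .letterLabels(length(stretches))
  lettersSorted <- vapply(seq_len(k), function(g) {
    covering <- vapply(stretches, function(s) s[1] <= g && g <= s[2], TRUE)
    paste(lab[covering], collapse = "")
  }, "")
  lettersOut <- character(k)
  lettersOut[ord] <- lettersSorted
  new("LetterGrouping", time = groups$time_h, mean = groups$mean,
      letters = lettersOut, alpha = alpha, order = as.integer(ord))
}

.splitLetters <- function(x) {
  ## split multi-letter strings into single letters; double letters
  ## ("aa", "ab") only appear past 26 subsets and are kept whole
  unlist(lapply(x, function(s) {
    if (nchar(s) <= 26L * 1L && !grepl("[^a-z]", s))
      strsplit(s, "")[[1]]
    else s
  }))
}

#' @rdname discriminationCount
setMethod("discriminationCount", "LetterGrouping", function(grouping) {
  length(unique(.splitLetters(grouping@letters)))
})

#' @rdname discriminationCount
setMethod("discriminationCount", "character", function(grouping) {
  length(unique(.splitLetters(grouping)))
})

#' Pairwise Pearson correlation with significance stars
#'
#' Two-sided t-test p-values; \code{"*"} marks p < 0.05 and \code{"**"}
#' p < 0.01, the convention of published sensor correlation tables.
#'
#' @param series named list of equal-length numeric vectors, or a
#'   matrix/data.frame with one series per column. All series need
#'   length >= 3 and nonzero variance.
#' @return a \linkS4class{CorrelationTable}.
#' @export
pearsonWithStars <- function(series) {
  x <- if (is.list(series) && !is.data.frame(series))
    do.call(cbind, series) else as.matrix(series)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x)
  if (n < 3L) stop("need series of length >= 3", call. = FALSE)
  zv <- apply(x, 2, var) == 0
  if (any(zv))
    stop("degenerate data: zero variance in series '",
         colnames(x)[zv][1], "'", call. = FALSE)
  r <- cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  stars <- matrix("", ncol(x), ncol(x), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  new("CorrelationTable", r = r, p = p, stars = stars, n = as.integer(n))
}

#' Loadings analysis of the E-nose mean-response matrix
#'
#' Principal components of the per-time channel means (centered, and by
#' default not variance-scaled, so high-variance channels dominate as
#' raw gas-sensor responses do). Channels are ranked by the magnitude of
#' their first-component loading, the usual screen for which sensors
#' carry the aroma signal.
#'
#' @param summaryMatrix time x channel matrix of mean responses
#'   (>= 3 times, >= 2 channels).
#' @param scale. logical, variance-scale before the decomposition
#'   (default \code{FALSE}).
#' @return list with \code{loadings} (channel x component),
#'   \code{varianceFractions}, \code{ranking} (channels by decreasing
#'   |PC1 loading|) and \code{rankDeficient} flag.
#' @export
enoseLoadings <- function(summaryMatrix, scale. = FALSE) {
  m <- as.matrix(summaryMatrix)
  if (nrow(m) < 3L || ncol(m) < 2L)
    stop("need >= 3 times and >= 2 channels", call. = FALSE)
  pr <- prcomp(m, center = TRUE, scale. = scale.)
  tol <- max(pr$sdev) * 1e-10
  keep <- pr$sdev > tol
  load <- pr$rotation[, keep, drop = FALSE]
  vf <- pr$sdev[keep]^2 / sum(pr$sdev^2)
  list(loadings = load,
       varianceFractions = vf,
       ranking = colnames(m)[order(-abs(load[, 1]))],
       rankDeficient = sum(keep) < min(dim(m)))
}

#' Rank sensor channels by the three-way screening evidence
#'
#' Orders channels by Duncan discrimination count (descending), then by
#' absolute correlation with the target series (descending), then by
#' absolute first-component loading (descending). The first element is
#' the channel the screening procedure selects.
#'
#' @param counts named integer vector of discrimination counts.
#' @param rWithTarget named numeric vector of correlations with the
#'   target (e.g. the plate-count log series).
#' @param pc1Loadings named numeric vector of first-component loadings.
#' @return character vector of channels, best first.
#' @export
rankSensors <- function(counts, rWithTarget, pc1Loadings) {
  ch <- names(counts)
  if (is.null(ch) || !setequal(ch, names(rWithTarget)) ||
      !setequal(ch, names(pc1Loadings)))
    stop("consistency error: the three inputs must cover the same channels",
         call. = FALSE)
  o <- order(-as.numeric(counts),
             -abs(as.numeric(rWithTarget[ch])),
             -abs(as.numeric(pc1Loadings[ch])))
  ch[o]
}
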