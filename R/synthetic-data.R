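## Synthetic-data generator. The emulated study design: juice stored at
## 4 degC for 7 days, sampled every 12 h (15 times), 20 replicate
## samples per time (15 train / 5 test), a 10-channel E-nose and a
## 9-channel E-tongue read on every sample, and plate counts following
## a Baranyi curve with a ~98 h lag. Sensor channels are affine
## transforms of the latent log-count curve plus independent Gaussian
## replicate noise; no residual between-channel covariance is modelled
## because none is published.

## Published per-time correlations between taste channels and the
## log count; used to calibrate taste-channel signal-to-noise.
.tasteTargetR <- c(sourness = 0.243, bitterness = -0.044,
                   astringency = 0.219, aftertaste_b = 0.092,
                   aftertaste_a = 0.166, umami = -0.578,
                   richness = 0.641, saltiness = -0.349,
                   sweetness = 0.772)

## Plausible taste-unit baselines for a potentiometric tongue readout.
.tasteIntercept <- c(sourness = 8, bitterness = 5, astringency = 4,
                     aftertaste_b = 2, aftertaste_a = 2, umami = 9,
                     richness = 6, saltiness = 7, sweetness = 10)

.tasteNoiseSd <- 2.0  # taste units, common to all taste channels

## Taste-channel drift: structured session drift (potentiometric
## tongues drift between measurement sessions) sized at 4x the
## mean-level replicate-noise variance. Each taste channel loads on
## exactly one of three drift factors (channels i, i+3, i+6 share
## factor i), so the drift occupies three comparable principal
## directions instead of collapsing into one.
.tasteDriftFactor <- 4

## Three unit-sd drift time courses, Gram-Schmidt-orthogonalized against
## the latent growth curve (and each other) over the sampling grid, so
## drift never masquerades as growth signal.
.driftBasis <- function(times, latent) {
  tt <- (times - min(times)) / diff(range(times))
  raw <- cbind(cos(2 * pi * tt), sin(2 * pi * tt), cos(4 * pi * tt))
  basis <- cbind(latent - mean(latent))
  out <- matrix(0, length(times), 3)
  for (k in 1:3) {
    v <- raw[, k] - mean(raw[, k])
    for (j in seq_len(ncol(basis))) {
      b <- basis[, j]
      v <- v - sum(v * b) / sum(b * b) * b
    }
    out[, k] <- v / sd(v)
    basis <- cbind(basis, v)
  }
  out
}

#' Default channel calibrations for the synthetic generator
#'
#' Every sensor channel is simulated as
#' \code{value = intercept + slope * latent(t) + N(0, noise_sd)} per
#' replicate. E-nose calibrations are derived from the packaged summary
#' panel: the slope maps the latent log-count span onto the channel's
#' observed response span (negative — gas responses fall as bacteria
#' grow) and the noise is the channel's median published standard
#' deviation. Taste-channel slopes are set so the expected per-time-mean
#' correlation with the latent curve matches the published taste/count
#' correlations (sweetness +0.77, umami negative, ...), at a fixed
#' replicate noise of 2 taste units. Taste channels additionally load
#' on three deterministic drift factors (columns \code{drift1..drift3})
#' orthogonal to the growth curve, emulating the structured
#' between-session variation that concentrates the fused decomposition
#' on a handful of components.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return data.frame with columns
#'   \code{channel, intercept, slope, noise_sd}.
#' @export
channelCalibrations <- function(design = studyDesign()) {
  stopifnot(is(design, "StudyDesign"))
  latent <- .curveValues("baranyi", .plateCountParams("baranyi"),
                         design@times)
  span <- latent[length(latent)] - latent[1]
  sdLatent <- sd(latent)

  enose <- enoseSummaryTable()
  en <- do.call(rbind, lapply(design@enoseChannels, function(ch) {
    sub <- enose[enose$channel == ch, ]
    sub <- sub[order(sub$time_h), ]
    if (!nrow(sub))
      stop("no packaged calibration source for E-nose channel '", ch, "'",
           call. = FALSE)
    slope <- (sub$mean[nrow(sub)] - sub$mean[1]) / span
    data.frame(channel = ch,
               intercept = sub$mean[1] - slope * latent[1],
               slope = slope,
               noise_sd = median(sub$sd))
  }))

  missingTaste <- setdiff(design@tasteChannels, names(.tasteTargetR))
  if (length(missingTaste))
    stop("consistency error: no calibration for taste channel '",
         missingTaste[1], "'", call. = FALSE)
  r <- .tasteTargetR[design@tasteChannels]
  ## slope s.t. cor(per-time mean, latent) ~= r: with growth signal
  ## s = |slope| * sd(latent), drift variance D and mean-level noise
  ## sd_m = noise_sd / sqrt(replicates), r = s / sqrt(s^2 + D + sd_m^2)
  sdm2 <- .tasteNoiseSd^2 / design@replicates
  D <- .tasteDriftFactor * sdm2
  s <- sqrt(D + sdm2) * abs(r) / sqrt(pmax(1 - r^2, 1e-6))
  idx <- seq_along(design@tasteChannels)
  sgn <- ifelse(idx %% 2L == 0L, -1, 1)
  dl <- matrix(0, length(idx), 3)
  dl[cbind(idx, ((idx - 1L) %% 3L) + 1L)] <- sgn * sqrt(D)
  ta <- data.frame(channel = design@tasteChannels,
                   intercept = unname(.tasteIntercept[design@tasteChannels]),
                   slope = unname(sign(r) * s / sdLatent),
                   noise_sd = .tasteNoiseSd,
                   drift1 = dl[, 1], drift2 = dl[, 2], drift3 = dl[, 3])
  en$drift1 <- en$drift2 <- en$drift3 <- 0
  out <- rbind(en, ta)
  rownames(out) <- NULL
  out
}

#' Simulate replicate plate counts around a growth curve
#'
#' @param params \linkS4class{GrowthParams} of the latent curve;
#'   defaults to the packaged plate-count Baranyi row.
#' @param kind one of \code{modelKinds()}.
#' @param design a \linkS4class{StudyDesign}.
#' @param noiseSd replicate noise in Log CFU/mL, >= 0.
#' @param seed integer seed; the same seed reproduces the panel
#'   bit-for-bit.
#' @return a \linkS4class{ReplicatePanel} with the single channel
#'   \code{"log_cfu"}.
#' @export
simulateCounts <- function(params = .plateCountParams("baranyi"),
                           kind = "baranyi", design = studyDesign(),
                           noiseSd = 0.1, seed) {
  kind <- .matchKind(kind)
  stopifnot(is(params, "GrowthParams"), is(design, "StudyDesign"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!is.finite(noiseSd) || noiseSd < 0)
    stop("invalid input: noiseSd must be >= 0", call. = FALSE)
  latent <- .curveValues(kind, params, design@times)
  nt <- length(design@times)
  nr <- design@replicates
  vals <- .withSeed(.childSeed(seed, 0L),
                    latent[rep(seq_len(nt), each = nr)] +
                      rnorm(nt * nr, 0, noiseSd))
  m <- matrix(vals, nrow = 1, dimnames = list("log_cfu", NULL))
  replicatePanel(m, time_h = rep(design@times, each = nr),
                 replicate = rep(seq_len(nr), times = nt))
}

#' Simulate a multi-channel sensor panel from a latent curve
#'
#' Each channel draws its own deterministic RNG sub-stream from the
#' master seed, so adding or dropping channels never changes the values
#' simulated for the others.
#'
#' @param latent a \linkS4class{CurveSeries} on \code{design@times}.
#' @param calibrations data.frame as returned by
#'   [channelCalibrations()].
#' @param design a \linkS4class{StudyDesign}.
#' @param seed integer master seed.
#' @return a \linkS4class{ReplicatePanel} with one row per calibrated
#'   channel.
#' @export
simulatePanel <- function(latent, calibrations, design = studyDesign(),
                          seed) {
  stopifnot(is(latent, "CurveSeries"), is(design, "StudyDesign"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(latent@times) != length(design@times) ||
      any(abs(latent@times - design@times) > 1e-9))
    stop("latent curve must be sampled on design@times", call. = FALSE)
  known <- c(design@enoseChannels, design@tasteChannels, "log_cfu")
  unknown <- setdiff(calibrations$channel, known)
  if (length(unknown))
    stop("consistency error: calibration channel '", unknown[1],
         "' is not in the design", call. = FALSE)
  if (any(calibrations$noise_sd < 0))
    stop("invalid input: noise_sd must be >= 0", call. = FALSE)
  nt <- length(design@times)
  nr <- design@replicates
  driftCols <- paste0("drift", 1:3)
  hasDrift <- all(driftCols %in% names(calibrations))
  basis <- .driftBasis(design@times, latent@values)
  m <- matrix(NA_real_, nrow(calibrations), nt * nr,
              dimnames = list(calibrations$channel, NULL))
  for (i in seq_len(nrow(calibrations))) {
    perTime <- calibrations$intercept[i] +
      calibrations$slope[i] * latent@values
    if (hasDrift)
      perTime <- perTime +
        basis %*% as.numeric(calibrations[i, driftCols])
    mu <- perTime[rep(seq_len(nt), each = nr)]
    m[i, ] <- .withSeed(.childSeed(seed, i),
                        mu + rnorm(nt * nr, 0, calibrations$noise_sd[i]))
  }
  replicatePanel(m, time_h = rep(design@times, each = nr),
                 replicate = rep(seq_len(nr), times = nt))
}

#' Generate a complete synthetic study dataset
#'
#' One call reproduces the whole emulated design: a latent Baranyi
#' growth curve, replicate plate counts (noise 0.1 Log CFU/mL), the 19
#' calibrated sensor channels, and the 15/5 train/test replicate split.
#'
#' @param seed integer master seed; identical seeds give identical
#'   datasets.
#' @param design a \linkS4class{StudyDesign}.
#' @return list with elements \code{panel} (20-channel
#'   \linkS4class{ReplicatePanel}: 19 sensors + \code{log_cfu}),
#'   \code{sensors}, \code{counts}, \code{latent}
#'   (\linkS4class{CurveSeries}), \code{calibrations}, \code{design},
#'   \code{trainReplicates} and \code{testReplicates}.
#' @examples
#' fx <- makeFixture(seed = 1)
#' dim(fx$panel)  # 20 channels x 300 samples
#' @export
makeFixture <- function(seed, design = studyDesign()) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  params <- .plateCountParams("baranyi")
  latent <- curveSeries(design@times, .curveValues("baranyi", params,
                                                   design@times))
  calib <- channelCalibrations(design)
  counts <- simulateCounts(params, "baranyi", design, noiseSd = 0.1,
                           seed = seed)
  sensors <- simulatePanel(latent, calib, design, seed = seed)
  stopifnot(identical(SummarizedExperiment::colData(counts)$time_h,
                      SummarizedExperiment::colData(sensors)$time_h))
  combined <- replicatePanel(
    rbind(SummarizedExperiment::assay(sensors, "response"),
          SummarizedExperiment::assay(counts, "response")),
    time_h = SummarizedExperiment::colData(sensors)$time_h,
    replicate = SummarizedExperiment::colData(sensors)$replicate)
  list(panel = combined, sensors = sensors, counts = counts,
       latent = latent, calibrations = calib, design = design,
       trainReplicates = seq_len(design@trainReplicates),
       testReplicates = seq.int(design@trainReplicates + 1L,
                                design@replicates))
}
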