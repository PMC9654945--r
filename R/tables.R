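## Accessors for the small reference tables shipped with the package:
## the published E-nose summary panel (means +/- sd, n = 20, with the
## original multiple-range-test letter column), the fused
## principal-component score table with its variance percentages, and
## the plate-count kinetic parameters of the four primary models.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "GrowthSense",
                      mustWork = FALSE)
  if (!nzchar(path))  # during in-source loading
    path <- file.path("inst", "extdata", file)
  if (!file.exists(path)) stop("packaged table not found: ", file)
  path
}

#' Packaged E-nose summary panel
#'
#' Per-time mean, standard deviation (n = 20) and published
#' homogeneous-subset letters for the ten gas-sensor channels of the
#' emulated cold-storage study.
#'
#' @return data.frame with columns
#'   \code{channel, time_h, mean, sd, n, letters}.
#' @export
enoseSummaryTable <- function() {
  utils::read.csv(.extdata("table3_enose_summary.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged fused principal-component score table
#'
#' Per-time scores of the four retained components from the fused
#' E-nose/E-tongue decomposition, their variance percentages, and the
#' published composite score column.
#'
#' @return list with \code{scores} (data.frame \code{time_h, pc1..pc4,
#'   score}) and \code{percent} (named numeric variance percentages).
#' @export
pcScoresTable <- function() {
  scores <- utils::read.csv(.extdata("table8_pc_scores.csv"),
                            stringsAsFactors = FALSE)
  v <- utils::read.csv(.extdata("table8_variance.csv"),
                       stringsAsFactors = FALSE)
  list(scores = scores, percent = setNames(v$percent, v$component))
}

#' Packaged plate-count kinetic parameters
#'
#' Fitted parameters of the four primary models for the plate-count log
#' series of the emulated study; the Baranyi row doubles as the default
#' latent growth curve of the synthetic-data generator.
#'
#' @return data.frame with columns
#'   \code{model, lag_h, mu_max_per_h, r2, rmse, n0, nmax}.
#' @export
plateCountParamsTable <- function() {
  utils::read.csv(.extdata("table1_platecount_params.csv"),
                  stringsAsFactors = FALSE)
}

## GrowthParams for one model row of the plate-count table
.plateCountParams <- function(kind = "baranyi") {
  tab <- plateCountParamsTable()
  row <- tab[tab$model == kind, ]
  if (!nrow(row)) stop("unknown model '", kind, "' in plate-count table")
  growthParams(row$n0, row$nmax, row$mu_max_per_h, row$lag_h)
}
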