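## Simple base-graphics views of the pipeline outputs.

#' Plot an MD profile against eccentricity
#'
#' MD per annulus at the annulus mid-radii, with the extension cut-off drawn
#' as a horizontal line.
#'
#' @param profile a \linkS4class{HenleMDProfile}.
#' @param cutoff MD cut-off to draw.
#' @param ... forwarded to \code{plot}.
#' @export
plotMDProfile <- function(profile, cutoff = 0.65, ...) {
  mids <- (0:13) + 0.5
  graphics::plot(mids, profile@md, type = "b", pch = 16,
                 xlab = "eccentricity (deg)", ylab = "MD",
                 ylim = c(0, max(1.4, profile@md, na.rm = TRUE)), ...)
  graphics::abline(h = cutoff, lty = 2)
}

#' Plot a circumferential retardation profile
#'
#' @param profile a \linkS4class{RetardationProfile}.
#' @param ... forwarded to \code{plot}.
#' @export
plotRetardationProfile <- function(profile, ...) {
  graphics::plot(profile@ecc, profile@retardation, type = "l",
                 xlab = "eccentricity (deg)", ylab = "retardation (deg)", ...)
}

#' Group box plots of a cohort measure
#'
#' Boxes follow \code{\link{boxplotSummary}}: quartile boxes, whiskers to the
#' most extreme non-outliers, outliers beyond 1.5 IQR drawn as points.
#'
#' @param cohort cohort data.frame from \code{\link{runPipeline}}.
#' @param measure column name to compare.
#' @param ... forwarded to \code{boxplot}.
#' @export
plotGroupBox <- function(cohort, measure = "extension", ...) {
  ok <- cohort$status == "ok"
  graphics::boxplot(cohort[[measure]][ok] ~ cohort$group[ok],
                    xlab = "group", ylab = measure, range = 1.5, ...)
}
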