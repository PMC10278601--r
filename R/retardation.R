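## Circumferential retardation profile and scalar summaries of the
## "donut"-shaped HFL retardation pattern.

#' Circumferentially averaged retardation profile
#'
#' Averages the retardation around the fovea centre per eccentricity bin.
#' Noise bias is controlled upstream by Stokes-space averaging (the depth
#' band and the 9 x 9 smoothing window): around a ring the fiber axis rotates
#' with azimuth, so Stokes vectors must not be averaged circumferentially
#' (their transverse components would cancel); the smoothed retardation
#' values are averaged instead. Bin membership is computed in degree space.
#' The per-annulus means over the exact 1-degree rings 1-2 to 7-8 degrees are
#' computed alongside the fine-binned curve.
#'
#' Typically \code{s} has first been smoothed with
#' \code{\link{smoothStokes}} (9 x 9 Stokes window).
#'
#' @param s a \linkS4class{StokesMap} (compensated, usually smoothed) or a
#'   \linkS4class{PolarizationMaps}.
#' @param center fovea centre in pixels (x, y).
#' @param binWidth eccentricity bin width in degrees.
#' @param maxEcc largest bin centre in degrees.
#' @return a \linkS4class{RetardationProfile}; empty bins are NA.
#' @export
circumferentialAverage <- function(s, center, binWidth = 0.25, maxEcc = 14) {
  if (is(s, "StokesMap")) {
    ret <- retardationFromStokes(s)
    ok <- s@valid & !is.na(ret)
    geom <- s@geometry
  } else {
    stopifnot(is(s, "PolarizationMaps"))
    ret <- s@retardation
    ok <- s@valid & !is.na(ret)
    geom <- s@geometry
  }
  grid <- degreeGrid(geom, center)

  binnedRetardation <- function(binIdx, nBins) {
    use <- ok & binIdx >= 1L & binIdx <= nBins
    idx <- binIdx[use]
    sums <- rowsum(ret[use], idx)
    n <- rowsum(rep(1, sum(use)), idx)
    out <- rep(NA_real_, nBins)
    out[as.integer(rownames(sums))] <- sums / n
    out
  }

  # fine curve: bin centres at multiples of binWidth (0, binWidth, ...)
  centers <- seq(0, maxEcc, by = binWidth)
  fineIdx <- as.integer(round(grid$ecc / binWidth)) + 1L
  curve <- binnedRetardation(fineIdx, length(centers))
  # exact 1-degree rings 1-2 .. 7-8
  ringIdx <- ifelse(grid$ecc >= 1 & grid$ecc < 8,
                    as.integer(floor(grid$ecc)), NA_integer_)
  ringIdx[is.na(ringIdx)] <- 0L
  ringVals <- binnedRetardation(ringIdx, 7L)
  names(ringVals) <- paste0(1:7, "-", 2:8)
  new("RetardationProfile", ecc = centers, retardation = curve,
      annulusMeans = ringVals)
}

#' Scalar metrics of a retardation profile
#'
#' Peak retardation and its eccentricity (over the full curve), the area
#' under the curve between 1 and 8 degrees eccentricity (trapezoid rule, with
#' the endpoints interpolated onto 1 and 8 exactly), and the per-annulus
#' means stored with the profile. Gaps (NA bins) inside [1, 8] make the AUC
#' undefined.
#'
#' @param profile a \linkS4class{RetardationProfile}.
#' @param aucRange numeric(2), integration range in degrees.
#' @return list with \code{peak} (deg), \code{peakEcc} (deg), \code{auc}
#'   (deg * deg, NA if undefined) and \code{annulusMeans} (deg).
#' @export
profileMetrics <- function(profile, aucRange = c(1, 8)) {
  ecc <- profile@ecc
  ret <- profile@retardation
  if (all(is.na(ret))) stop("empty profile")
  peak <- max(ret, na.rm = TRUE)
  peakEcc <- ecc[which.max(ret)]
  inside <- ecc > aucRange[1] & ecc < aucRange[2]
  covered <- ecc >= aucRange[1] & ecc <= aucRange[2]
  auc <- NA_real_
  if (any(covered) && !anyNA(ret[covered]) &&
      min(ecc[covered]) <= aucRange[1] + diff(aucRange) / 2) {
    ok <- !is.na(ret)
    ends <- stats::approx(ecc[ok], ret[ok], xout = aucRange, rule = 1)$y
    if (!anyNA(ends)) {
      xs <- c(aucRange[1], ecc[inside], aucRange[2])
      ys <- c(ends[1], ret[inside], ends[2])
      auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
    }
  }
  list(peak = peak, peakEcc = peakEcc, auc = auc,
       annulusMeans = profile@annulusMeans)
}
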