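## Volume-level operators: depth-dependent intensity threshold, DOPU over
## volumes, IS/OS segmentation refinement, en-face extraction, reference
## measurement, SNR estimation. Volumes are lists with arrays I, Q, U, V of
## dimension [depth, x, B-scan] (as returned by renderVolume); en-face maps
## and segmentation lines are [B-scan, x], matching StokesMap layout.

#' Depth-dependent intensity noise threshold
#'
#' Estimated from a central B-scan: pixels are sorted by intensity, the mean
#' and standard deviation of the darkest 80 percent are computed (assuming the
#' retinal signal lives in the brightest 20 percent), the first-row threshold
#' is mean + 7 * sd, and the threshold decreases linearly by 0.08 percent of
#' the standard deviation per pixel row to track the depth decay of the noise
#' floor.
#'
#' @slot base first-row threshold, intensity units.
#' @slot decayPerPx per-row decrement, intensity units.
#' @slot depthPx number of depth rows the profile covers.
#' @export
setClass("ThresholdProfile",
  representation(base = "numeric", decayPerPx = "numeric", depthPx = "integer"),
  validity = function(object) {
    if (length(object@base) != 1L || length(object@decayPerPx) != 1L)
      return("base and decayPerPx must be single values")
    if (object@decayPerPx < 0)
      return("decayPerPx must be non-negative")
    TRUE
  })

setMethod("show", "ThresholdProfile", function(object) {
  cat(sprintf("ThresholdProfile: base %.4g, decay %.4g per px over %d rows\n",
              object@base, object@decayPerPx, object@depthPx))
})

#' @rdname thresholdProfile
#' @param bscan intensity matrix [depth, x] of the central B-scan.
#' @param darkFraction fraction of darkest pixels defining the noise sample.
#' @param nSigma multiplier on the noise standard deviation.
#' @param decayFraction per-row decrement as a fraction of the noise sd.
#' @export
thresholdProfile <- function(bscan, darkFraction = 0.8, nSigma = 7,
                             decayFraction = 8e-4) {
  v <- sort(as.vector(bscan))
  if (!length(v)) stop("empty B-scan")
  k <- max(1L, floor(darkFraction * length(v)))
  dark <- v[seq_len(k)]
  ibar <- mean(dark)
  si <- stats::sd(dark)
  if (!is.finite(si) || si == 0) {
    warning("constant B-scan: zero noise sd, threshold set to the mean")
    si <- 0
  }
  new("ThresholdProfile", base = ibar + nSigma * si,
      decayPerPx = decayFraction * si, depthPx = nrow(bscan))
}

#' Evaluate a threshold profile at given depth rows
#'
#' Row k (1-based) has threshold base - (k - 1) * decayPerPx.
#'
#' @name thresholdProfile
#' @param tp a \linkS4class{ThresholdProfile}.
#' @param rows depth row indices (1-based); may be a matrix.
#' @return threshold values with the shape of \code{rows}.
#' @export
thresholdAt <- function(tp, rows) {
  tp@base - (rows - 1) * tp@decayPerPx
}

#' DOPU over a PS-OCT volume
#'
#' Computes the degree of polarization uniformity per B-scan slice
#' [depth, x] with a (cropped-border) kernel, default 10 x 10 pixels.
#'
#' @param vol a volume list as returned by \code{\link{renderVolume}}.
#' @param kernel integer(2), kernel size (depth, lateral).
#' @param tp optional \linkS4class{ThresholdProfile}; sub-threshold pixels are
#'   excluded from the kernel means.
#' @return array [depth, x, B-scan] of DOPU values.
#' @export
dopuVolume <- function(vol, kernel = c(10, 10), tp = NULL) {
  v <- vol$volume
  d <- dim(v$I)
  out <- array(NA_real_, d)
  thr <- if (is.null(tp)) NULL else thresholdAt(tp, seq_len(d[1]))
  for (b in seq_len(d[3])) {
    I <- v$I[, , b]
    valid <- is.finite(I) & I > 0
    if (!is.null(thr)) valid <- valid & I > thr
    out[, , b] <- dopuMap(list(I = I, Q = v$Q[, , b], U = v$U[, , b],
                               V = v$V[, , b], valid = valid), kernel)
  }
  out
}

# linear index into a [depth, x, b] array from a depth matrix [b, x];
# returned as a plain vector (a matrix would be mistaken for coordinate rows)
.volIndex <- function(depth, d) {
  nb <- nrow(depth); nx <- ncol(depth)
  xm <- matrix(rep(seq_len(nx), each = nb), nb)
  bm <- matrix(rep(seq_len(nb), nx), nb)
  as.vector(depth + (xm - 1) * d[1] + (bm - 1) * d[1] * d[2])
}

#' Refine an IS/OS segmentation line
#'
#' Per A-scan: pixels whose DOPU falls below \code{dopuCut} (depolarizing RPE)
#' are excluded, and the brightest remaining pixel within \code{halfWidth}
#' pixels of the initial line becomes the corrected position. Ties go to the
#' shallower pixel. A-scans with no admissible candidate keep the initial
#' position and are flagged.
#'
#' @param vol a volume list (see \code{\link{renderVolume}}).
#' @param dopu DOPU array from \code{\link{dopuVolume}}.
#' @param line initial segmentation line, depth indices [B-scan, x].
#' @param dopuCut DOPU below which pixels are treated as depolarizing.
#' @param halfWidth search half-width in pixels around the initial line.
#' @return list with the corrected \code{line} and a logical \code{flagged}
#'   matrix marking A-scans without candidates.
#' @export
refineIsos <- function(vol, dopu, line, dopuCut = 0.75, halfWidth = 8) {
  d <- dim(vol$volume$I)
  stopifnot(all(line >= 1), all(line <= d[1]))
  bestI <- matrix(-Inf, nrow(line), ncol(line))
  bestZ <- line
  found <- matrix(FALSE, nrow(line), ncol(line))
  for (off in seq.int(-halfWidth, halfWidth)) {
    z <- line + off
    inb <- z >= 1 & z <= d[1]
    z1 <- pmin(pmax(z, 1), d[1])
    idx <- .volIndex(z1, d)
    dv <- dopu[idx]
    ok <- inb & !is.na(dv) & dv >= dopuCut
    iv <- vol$volume$I[idx]
    take <- ok & iv > bestI           # strict: earlier (shallower) wins ties
    bestI[take] <- iv[take]
    bestZ[take] <- z[take]
    found <- found | ok
  }
  bestZ[!found] <- line[!found]
  list(line = bestZ, flagged = !found)
}

#' Extract an en-face Stokes map around a layer line
#'
#' Per A-scan, the Stokes components are averaged over a band of
#' \code{depthPx} pixels in depth centred on the segmentation line,
#' intersected with above-threshold pixels. A-scans whose band holds no
#' above-threshold pixel become invalid.
#'
#' @param vol a volume list (see \code{\link{renderVolume}}).
#' @param line depth-index matrix [B-scan, x].
#' @param tp optional \linkS4class{ThresholdProfile} for the intensity cut.
#' @param depthPx band height in pixels (default 5).
#' @param surface label for the returned map.
#' @return a \linkS4class{StokesMap} of dimension [B-scan, x].
#' @export
extractEnface <- function(vol, line, tp = NULL, depthPx = 5, surface = "ISOS") {
  d <- dim(vol$volume$I)
  half <- (depthPx - 1L) %/% 2L
  acc <- lapply(c("I", "Q", "U", "V"), function(x) matrix(0, nrow(line), ncol(line)))
  names(acc) <- c("I", "Q", "U", "V")
  cnt <- matrix(0L, nrow(line), ncol(line))
  for (off in seq.int(-half, depthPx - 1L - half)) {
    z <- line + off
    inb <- z >= 1 & z <= d[1]
    z1 <- pmin(pmax(z, 1), d[1])
    idx <- .volIndex(z1, d)
    iv <- vol$volume$I[idx]
    ok <- inb & if (is.null(tp)) is.finite(iv) else iv > thresholdAt(tp, z1)
    for (nm in names(acc)) {
      val <- vol$volume[[nm]][idx]
      acc[[nm]][ok] <- acc[[nm]][ok] + val[ok]
    }
    cnt[ok] <- cnt[ok] + 1L
  }
  valid <- cnt > 0L
  for (nm in names(acc)) {
    acc[[nm]][valid] <- acc[[nm]][valid] / cnt[valid]
    acc[[nm]][!valid] <- 0
  }
  .stokesMap(acc$I, acc$Q, acc$U, acc$V, valid, surface, vol$geometry)
}

#' Reference measurement for anterior compensation
#'
#' Per A-scan, takes the Stokes state at the single brightest pixel within a
#' depth range posterior to the RNFL and anterior to the layers of interest
#' (the surrogate for the RNFL-GCL to INL-OPL range). Ties go to the shallower
#' pixel; empty ranges give invalid pixels.
#'
#' @param vol a volume list (see \code{\link{renderVolume}}).
#' @param range integer(2), (first, last) depth row of the search range.
#' @return a \linkS4class{StokesMap} labelled "reference".
#' @export
referenceMeasurement <- function(vol, range = vol$refRange) {
  d <- dim(vol$volume$I)
  nb <- d[3]; nx <- d[2]
  out <- lapply(1:4, function(i) matrix(0, nb, nx))
  names(out) <- c("I", "Q", "U", "V")
  valid <- matrix(FALSE, nb, nx)
  lo <- max(1L, range[1]); hi <- min(d[1], range[2])
  if (lo <= hi) {
    bestI <- matrix(-Inf, nb, nx)
    bestZ <- matrix(lo, nb, nx)
    for (z in lo:hi) {
      zm <- matrix(z, nb, nx)
      idx <- .volIndex(zm, d)
      iv <- vol$volume$I[idx]
      take <- iv > bestI
      bestI[take] <- iv[take]
      bestZ[take] <- z
    }
    idx <- .volIndex(bestZ, d)
    for (nm in names(out)) out[[nm]] <- matrix(vol$volume[[nm]][idx], nb, nx)
    valid <- is.finite(bestI)
  }
  .stokesMap(out$I, out$Q, out$U, out$V, valid, "reference", vol$geometry)
}

#' Estimate the signal-to-noise ratio of an en-face plane
#'
#' Mean, over valid pixels, of the ratio between the intensity and the noise
#' threshold at the extraction depth. Returned as a linear (unitless) ratio.
#'
#' @param intensity en-face intensity matrix.
#' @param threshold scalar or matrix of threshold values at the line depth.
#' @param valid optional logical mask.
#' @return scalar SNR (linear ratio).
#' @export
estimateSnr <- function(intensity, threshold, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(intensity)
  if (!any(valid)) stop("no valid pixels for SNR estimation")
  if (all(threshold <= 0)) {
    warning("non-positive threshold: SNR is infinite")
    return(Inf)
  }
  r <- intensity / threshold
  mean(r[valid])
}
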