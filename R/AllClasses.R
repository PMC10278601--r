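#' @include RcppExports.R
NULL

#' Scan geometry of a PS-OCT en-face acquisition
#'
#' Field of view, pixel grid, and the angular-to-metric scale of the scan.
#' Pixels are anisotropic (the x and y pixel densities differ), so every
#' eccentricity or azimuth computation in the package works in degree space,
#' never in raw pixel space.
#'
#' @slot fieldDeg numeric(2), field of view in degrees, (x, y).
#' @slot gridPx integer(2), number of pixels, (x, y).
#' @slot mmPerDeg numeric(1), retinal millimetres per degree of visual angle.
#' @slot wavelengthNm numeric(1), centre wavelength of the source in nm.
#' @export
setClass("SceneGeometry",
  representation(fieldDeg = "numeric", gridPx = "integer",
                 mmPerDeg = "numeric", wavelengthNm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@fieldDeg) != 2L || any(object@fieldDeg <= 0))
      msg <- c(msg, "fieldDeg must be two positive values (x, y)")
    if (length(object@gridPx) != 2L || any(object@gridPx < 1L))
      msg <- c(msg, "gridPx must be two positive integers (x, y)")
    if (length(object@mmPerDeg) != 1L || object@mmPerDeg <= 0)
      msg <- c(msg, "mmPerDeg must be a single positive value")
    if (length(object@wavelengthNm) != 1L || object@wavelengthNm <= 0)
      msg <- c(msg, "wavelengthNm must be a single positive value")
    if (length(msg)) msg else TRUE
  })

#' En-face Stokes-vector map at a named retinal surface
#'
#' The pipeline's central currency: four matrices (I, Q, U, V) in arbitrary
#' intensity units, plus a validity mask. Matrices are laid out [row = y,
#' col = x]. In the measurement frame used throughout, the circularly
#' polarized input state maps onto +Q, so an unretarded sample returns
#' (I, Q, U, V) = I * (1, 1, 0, 0).
#'
#' @slot I,Q,U,V numeric matrices of identical dimension.
#' @slot valid logical matrix; FALSE marks sub-threshold or undefined pixels.
#' @slot surface character, label of the retinal surface (e.g. "ISOS").
#' @slot geometry a \linkS4class{SceneGeometry}.
#' @export
setClass("StokesMap",
  representation(I = "matrix", Q = "matrix", U = "matrix", V = "matrix",
                 valid = "matrix", surface = "character",
                 geometry = "SceneGeometry"),
  validity = function(object) {
    d <- dim(object@I)
    msg <- character()
    for (nm in c("Q", "U", "V", "valid"))
      if (!identical(dim(slot(object, nm)), d))
        msg <- c(msg, sprintf("dim(%s) differs from dim(I)", nm))
    if (!is.logical(object@valid))
      msg <- c(msg, "valid must be a logical matrix")
    if (!identical(d, rev(object@geometry@gridPx)))
      msg <- c(msg, "map dimension must equal (ny, nx) of the geometry grid")
    if (any(object@I[object@valid] < 0, na.rm = TRUE))
      msg <- c(msg, "I must be non-negative on valid pixels")
    if (length(msg)) msg else TRUE
  })

#' Paired retardation / axis-orientation en-face maps
#'
#' Retardation in degrees in [0, 90]; slow-axis orientation in degrees in
#' [-90, 90), half-turn periodic (theta and theta + 180 are the same axis).
#' Both are defined only where \code{valid} is TRUE.
#'
#' @slot retardation numeric matrix, degrees.
#' @slot axis numeric matrix, degrees.
#' @slot valid logical matrix.
#' @slot geometry a \linkS4class{SceneGeometry}.
#' @export
setClass("PolarizationMaps",
  representation(retardation = "matrix", axis = "matrix", valid = "matrix",
                 geometry = "SceneGeometry"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@retardation), dim(object@axis)) ||
        !identical(dim(object@retardation), dim(object@valid)))
      msg <- c(msg, "retardation, axis, valid must share dimensions")
    ret <- object@retardation[object@valid]
    ax <- object@axis[object@valid]
    if (any(ret < -1e-9 | ret > 90 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "retardation must lie in [0, 90] degrees where valid")
    if (any(ax < -90 - 1e-9 | ax >= 90 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "axis must lie in [-90, 90) degrees where valid")
    if (length(msg)) msg else TRUE
  })

#' A linear retarder on the Poincare sphere
#'
#' @slot retardation numeric(1), single-pass-equivalent retardance in degrees,
#'   in [0, 180).
#' @slot axis numeric(1), axis orientation in degrees, in [-90, 90).
#' @export
setClass("Retarder",
  representation(retardation = "numeric", axis = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@retardation) != 1L ||
        object@retardation < 0 || object@retardation >= 180)
      msg <- c(msg, "retardation must be a single value in [0, 180) degrees")
    if (length(object@axis) != 1L || object@axis < -90 || object@axis >= 90)
      msg <- c(msg, "axis must be a single value in [-90, 90) degrees")
    if (length(msg)) msg else TRUE
  })

#' Ground truth of one synthetic Henle-fiber scene
#'
#' Parameterizes everything the synthetic generator needs: where the fovea
#' sits, how far the fiber layer extends, the height and position of the
#' "donut" retardation peak, the nasal-temporal asymmetry, the anterior
#' (cornea + RNFL surrogate) retarder that corrupts both returned surfaces,
#' the noise level, and the global axis-orientation rotation unknown.
#'
#' @slot foveaCenter numeric(2), fovea position in pixels (x, y).
#' @slot hflExtension numeric(1), radial extension in degrees, in (0, 14].
#' @slot peakRetardation numeric(1), degrees, in [0, 45].
#' @slot peakEccentricity numeric(1), degrees, in (0, hflExtension).
#' @slot asymmetryRatio numeric(1), >= 1; horizontal over vertical extent.
#' @slot anteriorRetardation numeric(1), degrees.
#' @slot anteriorAxis numeric(1), degrees in [-90, 90).
#' @slot snrDb numeric(1), signal-to-noise-threshold ratio in dB (may be Inf).
#' @slot rotationOffset numeric(1), degrees added to every axis value.
#' @slot seed integer(1).
#' @export
setClass("HenleGroundTruth",
  representation(foveaCenter = "numeric", hflExtension = "numeric",
                 peakRetardation = "numeric", peakEccentricity = "numeric",
                 asymmetryRatio = "numeric", anteriorRetardation = "numeric",
                 anteriorAxis = "numeric", snrDb = "numeric",
                 rotationOffset = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@foveaCenter) != 2L)
      msg <- c(msg, "foveaCenter must be (x, y) in pixels")
    if (object@hflExtension <= 0 || object@hflExtension > 14)
      msg <- c(msg, "hflExtension must lie in (0, 14] degrees")
    if (object@peakEccentricity <= 0 ||
        object@peakEccentricity >= object@hflExtension)
      msg <- c(msg, "peakEccentricity must lie in (0, hflExtension)")
    if (object@peakRetardation < 0 || object@peakRetardation > 45)
      msg <- c(msg, "peakRetardation must lie in [0, 45] degrees")
    if (object@asymmetryRatio < 1)
      msg <- c(msg, "asymmetryRatio must be >= 1")
    if (object@anteriorAxis < -90 || object@anteriorAxis >= 90)
      msg <- c(msg, "anteriorAxis must lie in [-90, 90) degrees")
    if (length(msg)) msg else TRUE
  })

#' Mean-deviation (MD) profile over the 14 foveal annuli
#'
#' MD per 1-degree-wide annulus with inner radii 0..13 degrees, plus the
#' corrections that produced it: the fovea centre actually used (pixels), the
#' global axis rotation applied, and the anterior compensation offsets
#' (d retardation, d axis) selected by the grid search. NA entries mark annuli
#' with too few populated segments.
#'
#' @slot md numeric(14), unitless, >= 0 (NA allowed).
#' @slot center numeric(2), pixels (x, y).
#' @slot rotation numeric(1), degrees.
#' @slot offsets numeric(2), degrees (d retardation, d axis).
#' @export
setClass("HenleMDProfile",
  representation(md = "numeric", center = "numeric", rotation = "numeric",
                 offsets = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@md) != 14L)
      msg <- c(msg, "md must have one value per annulus (14)")
    if (any(object@md < 0 | object@md > 4, na.rm = TRUE))
      msg <- c(msg, "md values must lie in [0, 4]")
    if (length(object@center) != 2L)
      msg <- c(msg, "center must be (x, y) in pixels")
    if (length(object@offsets) != 2L)
      msg <- c(msg, "offsets must be (d retardation, d axis) in degrees")
    if (length(msg)) msg else TRUE
  })

#' Circumferentially averaged retardation profile
#'
#' Retardation (degrees) versus eccentricity (degrees) around the fovea
#' centre, obtained by Stokes-space averaging per eccentricity bin, plus the
#' per-annulus means over the exact 1-degree rings 1-2 to 7-8 degrees.
#'
#' @slot ecc numeric, bin centres in degrees.
#' @slot retardation numeric, mean retardation per bin in degrees (NA = empty).
#' @slot annulusMeans numeric(7), per-annulus mean retardation, degrees.
#' @export
setClass("RetardationProfile",
  representation(ecc = "numeric", retardation = "numeric",
                 annulusMeans = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@ecc) != length(object@retardation))
      msg <- c(msg, "ecc and retardation must have equal length")
    if (any(object@retardation < -1e-9 | object@retardation > 90 + 1e-9,
            na.rm = TRUE))
      msg <- c(msg, "retardation must lie in [0, 90] degrees")
    if (length(object@annulusMeans) != 7L)
      msg <- c(msg, "annulusMeans must cover the seven rings 1-2 .. 7-8 deg")
    if (length(msg)) msg else TRUE
  })

## ---- show methods -----------------------------------------------------------

setMethod("show", "SceneGeometry", function(object) {
  cat(sprintf("SceneGeometry: %g x %g deg on %d x %d px, %.4f mm/deg, %g nm\n",
              object@fieldDeg[1], object@fieldDeg[2],
              object@gridPx[1], object@gridPx[2],
              object@mmPerDeg, object@wavelengthNm))
})

setMethod("show", "StokesMap", function(object) {
  cat(sprintf("StokesMap '%s': %d x %d px, %.1f%% valid\n",
              object@surface, ncol(object@I), nrow(object@I),
              100 * mean(object@valid)))
})

setMethod("show", "PolarizationMaps", function(object) {
  ret <- object@retardation[object@valid]
  cat(sprintf("PolarizationMaps: %d x %d px, %.1f%% valid, retardation %.2f-%.2f deg\n",
              ncol(object@axis), nrow(object@axis), 100 * mean(object@valid),
              if (length(ret)) min(ret, na.rm = TRUE) else NA,
              if (length(ret)) max(ret, na.rm = TRUE) else NA))
})

setMethod("show", "Retarder", function(object) {
  cat(sprintf("Retarder: retardation %.2f deg, axis %.2f deg\n",
              object@retardation, object@axis))
})

setMethod("show", "HenleGroundTruth", function(object) {
  cat(sprintf(paste0("HenleGroundTruth: fovea (%.1f, %.1f) px, extension %.2f deg, ",
                     "peak %.2f deg @ %.2f deg,\n  asymmetry %.2f, anterior (%.1f deg @ %.1f deg), ",
                     "SNR %.1f dB, rotation %.1f deg, seed %d\n"),
              object@foveaCenter[1], object@foveaCenter[2], object@hflExtension,
              object@peakRetardation, object@peakEccentricity,
              object@asymmetryRatio, object@anteriorRetardation,
              object@anteriorAxis, object@snrDb, object@rotationOffset,
              object@seed))
})

setMethod("show", "HenleMDProfile", function(object) {
  cat("HenleMDProfile (annuli 0-1 .. 13-14 deg):\n")
  cat(" ", paste(sprintf("%.2f", object@md), collapse = " "), "\n")
  cat(sprintf("  center (%.1f, %.1f) px, rotation %.1f deg, offsets (%g, %g) deg\n",
              object@center[1], object@center[2], object@rotation,
              object@offsets[1], object@offsets[2]))
})

setMethod("show", "RetardationProfile", function(object) {
  cat(sprintf("RetardationProfile: %d bins, peak %.2f deg at %.2f deg eccentricity\n",
              length(object@ecc), max(object@retardation, na.rm = TRUE),
              object@ecc[which.max(object@retardation)]))
})

## ---- accessors --------------------------------------------------------------

#' @describeIn StokesMap-accessors validity mask of a map object
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Accessors for map objects
#'
#' @param x a \linkS4class{StokesMap} or \linkS4class{PolarizationMaps}.
#' @name StokesMap-accessors
NULL

#' @rdname StokesMap-accessors
#' @export
setMethod("validMask", "StokesMap", function(x) x@valid)

#' @rdname StokesMap-accessors
#' @export
setMethod("validMask", "PolarizationMaps", function(x) x@valid)

#' @rdname StokesMap-accessors
#' @param component one of "I", "Q", "U", "V".
#' @export
stokesComponent <- function(x, component = c("I", "Q", "U", "V")) {
  stopifnot(is(x, "StokesMap"))
  slot(x, match.arg(component))
}

#' @rdname StokesMap-accessors
#' @export
retardationMap <- function(x) {
  stopifnot(is(x, "PolarizationMaps"))
  x@retardation
}

#' @rdname StokesMap-accessors
#' @export
axisMap <- function(x) {
  stopifnot(is(x, "PolarizationMaps"))
  x@axis
}

#' Accessors for MD profiles
#'
#' @param x a \linkS4class{HenleMDProfile}.
#' @return \code{mdValues}: numeric(14), MD per annulus (inner radii 0..13
#'   degrees); \code{mdCenter}: the corrected fovea centre in pixels;
#'   \code{mdRotation}: the applied axis rotation in degrees;
#'   \code{mdOffsets}: the selected compensation offsets in degrees.
#' @export
mdValues <- function(x) {
  stopifnot(is(x, "HenleMDProfile"))
  x@md
}

#' @rdname mdValues
#' @export
mdCenter <- function(x) {
  stopifnot(is(x, "HenleMDProfile"))
  x@center
}

#' @rdname mdValues
#' @export
mdRotation <- function(x) {
  stopifnot(is(x, "HenleMDProfile"))
  x@rotation
}

#' @rdname mdValues
#' @export
mdOffsets <- function(x) {
  stopifnot(is(x, "HenleMDProfile"))
  x@offsets
}
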