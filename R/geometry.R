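#' Construct a scan geometry
#'
#' Defaults describe a macular volume scan covering 28 (x) by 21 (y) degrees
#' of visual angle on a 1024 x 250 pixel grid, with the standard-eye scale of
#' 8 mm per 28 degrees and a centre wavelength of 860 nm. Note that the pixel
#' densities in x and y differ (1024/28 vs 250/21 px per degree), so all
#' eccentricity computations are carried out in degree space.
#'
#' @param fieldDeg numeric(2), field of view (x, y) in degrees.
#' @param gridPx numeric(2), grid size (x, y) in pixels.
#' @param mmPerDeg retinal mm per degree of visual angle.
#' @param wavelengthNm source centre wavelength in nm.
#' @return a \linkS4class{SceneGeometry}.
#' @examples
#' geom <- sceneGeometry()
#' pxPerDeg(geom)
#' @export
sceneGeometry <- function(fieldDeg = c(28, 21), gridPx = c(1024, 250),
                          mmPerDeg = 8 / 28, wavelengthNm = 860) {
  new("SceneGeometry", fieldDeg = as.numeric(fieldDeg),
      gridPx = as.integer(gridPx), mmPerDeg = as.numeric(mmPerDeg),
      wavelengthNm = as.numeric(wavelengthNm))
}

#' @rdname sceneGeometry
#' @param geom a \linkS4class{SceneGeometry}.
#' @return \code{pxPerDeg}: pixels per degree, named (x, y).
#' @export
pxPerDeg <- function(geom) {
  c(x = geom@gridPx[1] / geom@fieldDeg[1], y = geom@gridPx[2] / geom@fieldDeg[2])
}

# pixel-centre coordinates in degrees, along x (columns) and y (rows)
xDeg <- function(geom) (seq_len(geom@gridPx[1]) - 0.5) * geom@fieldDeg[1] / geom@gridPx[1]
yDeg <- function(geom) (seq_len(geom@gridPx[2]) - 0.5) * geom@fieldDeg[2] / geom@gridPx[2]

# pixel position (x, y) -> degrees; accepts fractional pixel coordinates
pxToDegXY <- function(geom, px) {
  p <- pxPerDeg(geom)
  c((px[1] - 0.5) / p["x"], (px[2] - 0.5) / p["y"])
}

#' Wrap an axis orientation into [-90, 90)
#'
#' Axis orientations are half-turn periodic: theta and theta + 180 describe
#' the same physical axis.
#'
#' @param theta angle(s) in degrees.
#' @return wrapped angle(s) in degrees.
#' @export
wrapAxis <- function(theta) ((theta + 90) %% 180) - 90

#' Degree-space pixel fields around a centre
#'
#' Computes, for every pixel, the eccentricity (degrees) and azimuth angle
#' (degrees in [0, 360)) relative to a centre given in pixel coordinates.
#' Azimuth 0 points along the upward vertical through the centre and increases
#' counterclockwise.
#'
#' @param geom a \linkS4class{SceneGeometry}.
#' @param center numeric(2), centre in pixels (x, y); may be fractional.
#' @param asymmetryRatio optional >= 1; if given, the returned \code{eccEff}
#'   field divides the horizontal degree offset by this factor (used by the
#'   generator to widen the pattern nasally/temporally).
#' @return list with matrices \code{ecc}, \code{phi} (and \code{eccEff}).
#' @export
degreeGrid <- function(geom, center, asymmetryRatio = 1) {
  cd <- pxToDegXY(geom, center)
  dx <- matrix(xDeg(geom) - cd[1], nrow = geom@gridPx[2],
               ncol = geom@gridPx[1], byrow = TRUE)
  dyup <- matrix(cd[2] - yDeg(geom), nrow = geom@gridPx[2],
                 ncol = geom@gridPx[1])
  ecc <- sqrt(dx^2 + dyup^2)
  phi <- (atan2(-dx, dyup) * 180 / pi) %% 360
  out <- list(ecc = ecc, phi = phi)
  if (asymmetryRatio != 1)
    out$eccEff <- sqrt((dx / asymmetryRatio)^2 + dyup^2)
  else
    out$eccEff <- ecc
  out
}

#' Angular eccentricity to retinal distance and area
#'
#' Under the standard-eye scan geometry (28 degrees across 8 mm), an
#' eccentricity of e degrees corresponds to a retinal radius of e * mmPerDeg
#' and a circular area of pi * (e * mmPerDeg)^2. For the default geometry,
#' 5 and 12 degrees give 6.4 and 36.9 mm^2.
#'
#' @param ecc eccentricity in degrees.
#' @param geom a \linkS4class{SceneGeometry}.
#' @return \code{eccDegToMm}: radius in mm; \code{eccAreaMm2}: area in mm^2.
#' @examples
#' eccAreaMm2(5)
#' eccAreaMm2(12)
#' @export
eccDegToMm <- function(ecc, geom = sceneGeometry()) {
  stopifnot(all(ecc >= 0))
  ecc * geom@mmPerDeg
}

#' @rdname eccDegToMm
#' @export
eccAreaMm2 <- function(ecc, geom = sceneGeometry()) {
  pi * eccDegToMm(ecc, geom)^2
}
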