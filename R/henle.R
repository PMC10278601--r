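## The azimuthal mean-deviation (MD) statistic and the four-step correction
## pipeline (global axis rotation, fovea-centre refinement, anterior
## compensation offsets, re-centering), plus HFL lateral-extension estimation.
##
## Axis orientations are half-turn periodic, so before any averaging the axis
## theta is mapped onto the full unit circle by doubling: Z = exp(i * 2 *
## theta). A perfectly radial Henle pattern then traces the ideal curve
## Z_ideal(phi) = exp(i * 2 * theta_ideal(phi)) with theta_ideal(phi) =
## (phi mod 180) - 90 (axis -90 at azimuth 0), completing two full
## oscillations of Re Z and Im Z per turn. For a completely random axis map
## the per-segment means of Z vanish and the mean L1 distance to the ideal
## curve converges to E|cos| + E|sin| = 4/pi ~ 1.27 (the printed noise floor
## of 1.3); for a perfect pattern it is 0.

#' Ideal radial Henle axis pattern
#'
#' \code{idealAxis} gives the axis orientation of a radial fiber pattern at
#' azimuth phi: theta = (phi mod 180) - 90 degrees, so azimuth 0 carries axis
#' -90. \code{idealPattern} maps it onto the unit circle with the half-turn
#' doubling, Z = exp(i * 2 * theta * pi / 180).
#'
#' @param phi azimuth angle(s) in degrees.
#' @return \code{idealAxis}: degrees in [-90, 90); \code{idealPattern}:
#'   complex on the unit circle.
#' @examples
#' idealAxis(c(0, 90, 180))
#' @export
idealAxis <- function(phi) ((phi %% 180) - 90)

#' @rdname idealAxis
#' @export
idealPattern <- function(phi) axisToComplex(idealAxis(phi))

#' Map axis orientations onto the unit circle
#'
#' Z = exp(i * 2 * theta), with theta in degrees. The doubling resolves the
#' half-turn periodicity of axis data: theta and theta + 180 map to the same
#' point, uniformly random axes spread uniformly over the full circle (so
#' their mean vanishes), and averaging in Z-space is the circular-statistics
#' mean for axial data.
#'
#' @param theta axis orientation(s) in degrees; NA propagates.
#' @return complex with unit modulus.
#' @export
axisToComplex <- function(theta) exp(2i * theta * pi / 180)

# ideal-curve samples at segment centres
.idealSegments <- function(nSegments) {
  phi <- (seq_len(nSegments) - 0.5) * 360 / nSegments
  z <- idealPattern(phi)
  list(phi = phi, re = Re(z), im = Im(z))
}

# resolve an axis input (PolarizationMaps, or matrix + valid + geometry)
.resolveAxis <- function(x, valid, geometry) {
  if (is(x, "PolarizationMaps"))
    return(list(axis = x@axis, valid = x@valid, geom = x@geometry))
  stopifnot(is.matrix(x), is(geometry, "SceneGeometry"))
  if (is.null(valid)) valid <- is.finite(x)
  list(axis = x, valid = valid & is.finite(x), geom = geometry)
}

# segment sums of Z = exp(2i theta) over an annulus; explicit coordinate
# vectors allow cropped maps
.segSums <- function(axis, valid, xdeg, ydeg, centerDeg, rin, rout, nSegments) {
  t2 <- 2 * axis * pi / 180
  re <- cos(t2); im <- sin(t2)
  re[!valid] <- 0; im[!valid] <- 0
  .segment_sums_cpp(re, im, valid, xdeg, ydeg,
                    centerDeg[1], centerDeg[2], rin, rout, as.integer(nSegments))
}

.mdFromSums <- function(ss, ideal, minSegFrac) {
  ok <- ss$n > 0L
  if (!any(ok) || sum(ok) < minSegFrac * length(ss$n)) return(NA_real_)
  mr <- ss$sumRe[ok] / ss$n[ok]
  mi <- ss$sumIm[ok] / ss$n[ok]
  mean(abs(mr - ideal$re[ok]) + abs(mi - ideal$im[ok]))
}

#' Per-segment azimuthal profile of the axis pattern
#'
#' Divides an annulus (radii in degrees, pixel membership computed in degree
#' space) into equal azimuthal segments and averages Z = exp(i 2 theta) per
#' segment over valid pixels.
#'
#' @param x a \linkS4class{PolarizationMaps}, or an axis matrix in degrees.
#' @param center fovea centre in pixels (x, y); may be fractional.
#' @param annulus numeric(2), inner and outer radius in degrees.
#' @param nSegments number of azimuthal segments (default 360, 1 degree each).
#' @param valid,geometry required when \code{x} is a plain matrix.
#' @return data.frame with segment centre azimuth \code{phi}, mean \code{re}
#'   and \code{im} of Z (NA for empty segments), and pixel count \code{n}.
#' @export
azimuthalProfile <- function(x, center, annulus = c(1, 2), nSegments = 360L,
                             valid = NULL, geometry = NULL) {
  a <- .resolveAxis(x, valid, geometry)
  ss <- .segSums(a$axis, a$valid, xDeg(a$geom), yDeg(a$geom),
                 pxToDegXY(a$geom, center), annulus[1], annulus[2], nSegments)
  ideal <- .idealSegments(nSegments)
  re <- ifelse(ss$n > 0, ss$sumRe / ss$n, NA_real_)
  im <- ifelse(ss$n > 0, ss$sumIm / ss$n, NA_real_)
  data.frame(phi = ideal$phi, re = re, im = im, n = ss$n)
}

#' Mean deviation (MD) from the ideal Henle pattern
#'
#' For each non-empty azimuthal segment s of the annulus, the distance
#' d_s = |Re Zbar_s - Re Z_ideal(phi_s)| + |Im Zbar_s - Im Z_ideal(phi_s)|
#' is computed between the segment-averaged Z and the ideal radial pattern;
#' MD is the mean of d_s over non-empty segments. MD is ~0 for a perfect
#' radial pattern and ~4/pi (~1.27, printed as 1.3) for a fully random axis
#' map. Annuli with fewer than \code{minSegFrac} non-empty segments are
#' undefined (NA).
#'
#' @inheritParams azimuthalProfile
#' @param minSegFrac minimum fraction of non-empty segments.
#' @return scalar MD (NA if undefined).
#' @export
computeMD <- function(x, center, annulus = c(1, 2), nSegments = 360L,
                      valid = NULL, geometry = NULL, minSegFrac = 0.5) {
  a <- .resolveAxis(x, valid, geometry)
  ss <- .segSums(a$axis, a$valid, xDeg(a$geom), yDeg(a$geom),
                 pxToDegXY(a$geom, center), annulus[1], annulus[2], nSegments)
  .mdFromSums(ss, .idealSegments(nSegments), minSegFrac)
}

#' MD over the 14 foveal annuli
#'
#' Computes the MD in 1-degree-wide annuli with inner radii 0 to 13 degrees.
#'
#' @inheritParams computeMD
#' @param rotation global axis rotation already applied (recorded only).
#' @param offsets compensation offsets already applied (recorded only).
#' @return a \linkS4class{HenleMDProfile}.
#' @export
mdProfile <- function(x, center, nSegments = 360L, valid = NULL,
                      geometry = NULL, minSegFrac = 0.5,
                      rotation = 0, offsets = c(0, 0)) {
  md <- vapply(0:13, function(r)
    computeMD(x, center, c(r, r + 1), nSegments, valid, geometry, minSegFrac),
    numeric(1))
  new("HenleMDProfile", md = md, center = as.numeric(center),
      rotation = as.numeric(rotation), offsets = as.numeric(offsets))
}

#' Global axis-rotation correction
#'
#' The instrument reports only relative axis orientations, offset by an
#' unknown constant. The correction finds the constant to add so that the
#' measured pattern aligns with the ideal anchor (axis -90 at azimuth 0,
#' equivalently the +90/-90 wrap sits at azimuth 0), using the annulus
#' between 1 and 2 degrees: an exhaustive 1-degree sweep over the 180
#' candidate rotations minimizing the MD, followed by a continuous
#' circular-mean phase refinement that is kept only when it lowers the MD
#' further.
#'
#' @inheritParams computeMD
#' @return list with the rotated maps (\code{pol}, when the input was a
#'   \linkS4class{PolarizationMaps}), the \code{rotation} in degrees in
#'   [-90, 90), and the achieved \code{md}.
#' @export
rotationCorrection <- function(x, center, annulus = c(1, 2), nSegments = 360L,
                               valid = NULL, geometry = NULL,
                               minSegFrac = 0.5) {
  a <- .resolveAxis(x, valid, geometry)
  ss <- .segSums(a$axis, a$valid, xDeg(a$geom), yDeg(a$geom),
                 pxToDegXY(a$geom, center), annulus[1], annulus[2], nSegments)
  ideal <- .idealSegments(nSegments)
  ok <- ss$n > 0L
  if (!any(ok) || sum(ok) < minSegFrac * length(ss$n)) {
    warning("no discernible pattern in the rotation annulus; rotation 0")
    rot <- 0; md <- NA_real_
  } else {
    zbar <- complex(real = ss$sumRe[ok] / ss$n[ok],
                    imaginary = ss$sumIm[ok] / ss$n[ok])
    zi <- complex(real = ideal$re[ok], imaginary = ideal$im[ok])
    mdAt <- function(rho) {
      z <- zbar * exp(2i * rho * pi / 180)
      mean(abs(Re(z) - Re(zi)) + abs(Im(z) - Im(zi)))
    }
    cand <- 0:179
    mds <- vapply(cand, mdAt, numeric(1))
    best <- which.min(mds)
    rot <- cand[best]; md <- mds[best]
    # continuous refinement: phase of the correlation with the ideal curve
    rho_cm <- 0.5 * Arg(sum(zi * Conj(zbar))) * 180 / pi
    md_cm <- mdAt(rho_cm)
    if (is.finite(md_cm) && md_cm < md) {
      rot <- rho_cm; md <- md_cm
    }
  }
  rot <- wrapAxis(rot)
  out <- list(rotation = rot, md = md)
  if (is(x, "PolarizationMaps")) {
    ax <- wrapAxis(x@axis + rot)
    ax[!x@valid] <- 0
    out$pol <- initialize(x, axis = ax)
  }
  out
}

# apply a rotation to a PolarizationMaps axis
.rotatePol <- function(pol, rotation) {
  ax <- wrapAxis(pol@axis + rotation)
  ax[!pol@valid] <- 0
  initialize(pol, axis = ax)
}

#' Iterative fovea-centre refinement
#'
#' Every pixel in a window (default 31 x 31) around the current centre is
#' tried as a new centre; the MD in the 1-2 degree annulus is minimized, ties
#' going to the smallest (|dy|, |dx|, dy, dx) displacement; the search is
#' repeated around the winning pixel until centre and MD no longer change.
#'
#' @inheritParams computeMD
#' @param window odd window edge length in pixels.
#' @param maxIter iteration cap; non-convergence returns the best-so-far with
#'   a warning.
#' @return list with \code{center} (pixels), \code{md}, \code{iterations},
#'   \code{converged}.
#' @export
refineCenter <- function(x, center, annulus = c(1, 2), window = 31L,
                         nSegments = 360L, valid = NULL, geometry = NULL,
                         minSegFrac = 0.5, maxIter = 20L) {
  a <- .resolveAxis(x, valid, geometry)
  stopifnot(window %% 2 == 1)
  half <- (as.integer(window) - 1L) %/% 2L
  t2 <- 2 * a$axis * pi / 180
  re <- cos(t2); im <- sin(t2)
  re[!a$valid] <- 0; im[!a$valid] <- 0
  ideal <- .idealSegments(nSegments)
  xd <- xDeg(a$geom); yd <- yDeg(a$geom)
  cur <- round(as.numeric(center))
  cur[1] <- min(max(cur[1], 1L), a$geom@gridPx[1])
  cur[2] <- min(max(cur[2], 1L), a$geom@gridPx[2])
  # candidate preference order within a window: smallest displacement first
  g <- expand.grid(dy = seq.int(-half, half), dx = seq.int(-half, half))
  ord <- order(abs(g$dy), abs(g$dx), g$dy, g$dx)
  curMd <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    W <- .window_md_cpp(re, im, a$valid, xd, yd, cur[1], cur[2], half,
                        annulus[1], annulus[2], as.integer(nSegments),
                        ideal$re, ideal$im, minSegFrac)
    mds <- W[cbind(g$dy + half + 1L, g$dx + half + 1L)]
    fin <- which(is.finite(mds[ord]))
    if (!length(fin)) {
      warning("MD undefined over the whole search window")
      break
    }
    mmin <- min(mds[ord][fin])
    pick <- ord[fin[which(mds[ord][fin] == mmin)[1]]]
    new_c <- c(cur[1] + g$dx[pick], cur[2] + g$dy[pick])
    if (all(new_c == cur) && mmin >= curMd - 0) {
      curMd <- min(curMd, mmin)
      converged <- TRUE
      break
    }
    cur <- new_c
    curMd <- mmin
  }
  if (!converged && iter >= maxIter)
    warning("center refinement did not converge; returning best-so-far")
  list(center = cur, md = curMd, iterations = iter, converged = converged)
}

# compensation + axis extraction on raw matrices (cropped fast path);
# rotation added afterwards; returns axis + valid
.compensatedAxis <- function(tQ, tU, tV, tI, tValid, rQ, rU, rV, rI, rValid,
                             offsets, rotation) {
  ok <- rValid & tValid & rI > 0
  q <- rQ / rI; u <- rU / rI; v <- rV / rI
  mag <- sqrt(q^2 + u^2 + v^2)
  ok <- ok & is.finite(mag) & mag > 1e-12
  dA <- 0.5 * acos(pmin(pmax(ifelse(ok, q / mag, 0), -1), 1)) * 180 / pi +
    offsets[1]
  tA <- 0.5 * atan2(u, -v) * 180 / pi + offsets[2]
  dA[!ok] <- 0; tA[!ok] <- 0
  rot <- .rotQUV(tQ, tU, tV, -dA, tA)
  tr <- sqrt(rot$U^2 + rot$V^2)
  ok <- ok & is.finite(tr) & tr > 1e-12
  ax <- wrapAxis(0.5 * atan2(rot$U, -rot$V) * 180 / pi + rotation)
  ax[!ok] <- 0
  list(axis = ax, valid = ok)
}

#' Grid search over anterior-compensation offsets
#'
#' The anterior compensation may be incomplete because the reference
#' measurement is noisy. The en-face maps are therefore recompensated
#' repeatedly with two separate offsets added to the reference retardation
#' and axis orientation, each ranging over -5 to +5 degrees in 1-degree
#' steps; the offset pair minimizing the MD in the 1-2 degree annulus wins
#' (ties: smallest |d retardation| + |d axis|, then lexicographic).
#'
#' Because an axis offset on the reference shifts the extracted axis map in a
#' way partially degenerate with the global rotation, the rotation is
#' re-aligned per candidate (analytic circular-mean phase alignment with the
#' ideal curve) before the MD is evaluated, unless
#' \code{reestimateRotation = FALSE}; the final rotation belonging to the
#' winning offsets is returned.
#'
#' @param target \linkS4class{StokesMap} at IS/OS (uncompensated).
#' @param reference \linkS4class{StokesMap} at the reference surface.
#' @param rotation global axis rotation (degrees) applied after extraction;
#'   with \code{reestimateRotation} this is the fallback starting value.
#' @param center fovea centre in pixels.
#' @param annulus,nSegments,minSegFrac as in \code{\link{computeMD}}.
#' @param offsetGrid candidate offsets in degrees.
#' @param reestimateRotation re-align the global rotation per candidate.
#' @return list with \code{offsets} (degrees), \code{rotation} (degrees), the
#'   fully corrected \linkS4class{PolarizationMaps} \code{pol}, the
#'   compensated \linkS4class{StokesMap} \code{stokes}, and the achieved
#'   \code{md}.
#' @export
offsetSearch <- function(target, reference, rotation, center,
                         annulus = c(1, 2), offsetGrid = -5:5,
                         nSegments = 360L, minSegFrac = 0.5,
                         reestimateRotation = TRUE) {
  geom <- target@geometry
  cd <- pxToDegXY(geom, center)
  xd <- xDeg(geom); yd <- yDeg(geom)
  margin <- 0.3
  cols <- which(abs(xd - cd[1]) <= annulus[2] + margin)
  rows <- which(abs(yd - cd[2]) <= annulus[2] + margin)
  if (!length(cols) || !length(rows)) stop("annulus outside the field")
  crop <- function(m) m[rows, cols, drop = FALSE]
  tQ <- crop(target@Q); tU <- crop(target@U); tV <- crop(target@V)
  tI <- crop(target@I); tval <- crop(target@valid)
  rQ <- crop(reference@Q); rU <- crop(reference@U); rV <- crop(reference@V)
  rI <- crop(reference@I); rval <- crop(reference@valid)
  ideal <- .idealSegments(nSegments)
  ziC <- complex(real = ideal$re, imaginary = ideal$im)
  g <- expand.grid(dd = offsetGrid, dt = offsetGrid)
  g <- g[order(abs(g$dd) + abs(g$dt), g$dd, g$dt), ]
  bestMd <- Inf
  best <- NULL
  bestRot <- rotation
  for (k in seq_len(nrow(g))) {
    ca <- .compensatedAxis(tQ, tU, tV, tI, tval, rQ, rU, rV, rI, rval,
                           c(g$dd[k], g$dt[k]), 0)
    ss <- .segSums(ca$axis, ca$valid, xd[cols], yd[rows], cd,
                   annulus[1], annulus[2], nSegments)
    ok <- ss$n > 0L
    if (!any(ok) || sum(ok) < minSegFrac * length(ss$n)) next
    zbar <- complex(real = ss$sumRe[ok] / ss$n[ok],
                    imaginary = ss$sumIm[ok] / ss$n[ok])
    zi <- ziC[ok]
    rho <- if (reestimateRotation)
      0.5 * Arg(sum(zi * Conj(zbar))) * 180 / pi else rotation
    z <- zbar * exp(2i * rho * pi / 180)
    md <- mean(abs(Re(z) - Re(zi)) + abs(Im(z) - Im(zi)))
    if (is.finite(md) && md < bestMd) {
      bestMd <- md
      best <- c(g$dd[k], g$dt[k])
      bestRot <- wrapAxis(rho)
    }
  }
  if (is.null(best)) stop("MD undefined for every offset candidate")
  stokes <- compensateAnterior(target, reference, best)
  pol <- .rotatePol(polarizationFromStokes(stokes), bestRot)
  list(offsets = best, rotation = bestRot, pol = pol, stokes = stokes,
       md = bestMd)
}

#' Full four-step correction and MD profile
#'
#' Runs the correction pipeline in order: (1) global axis rotation anchored
#' in the 1-2 degree annulus, (2) iterative fovea-centre refinement, (3) grid
#' search over anterior-compensation offsets with recompensation, (4) centre
#' refinement again; then computes the MD for all 14 annuli around the final
#' centre. Because a residual compensation error biases the centre estimate
#' and vice versa, steps (3)-(4) are repeated until offsets and centre reach
#' a fixed point (at most \code{maxRounds} rounds); the first round is the
#' canonical four-step sequence.
#'
#' @param dataset list with \code{isos} and \code{reference}
#'   (\linkS4class{StokesMap}s) and \code{initialCenter} (pixels), e.g. a
#'   subject from \code{\link{simulateCohort}} (fields \code{scene$isos},
#'   \code{scene$reference}, \code{initialCenter}).
#' @param annulus correction annulus in degrees.
#' @param window centre-search window edge (pixels).
#' @param offsetGrid compensation offset candidates (degrees).
#' @param nSegments azimuthal segments per annulus.
#' @param minSegFrac minimum fraction of non-empty segments per annulus.
#' @param maxRounds cap on offset/centre rounds.
#' @return list with \code{profile} (a \linkS4class{HenleMDProfile}),
#'   \code{pol} (corrected \linkS4class{PolarizationMaps}), \code{stokes}
#'   (compensated \linkS4class{StokesMap}), \code{rotation}, \code{center},
#'   \code{offsets}.
#' @export
fullCorrection <- function(dataset, annulus = c(1, 2), window = 31L,
                           offsetGrid = -5:5, nSegments = 360L,
                           minSegFrac = 0.5, maxRounds = 4L) {
  isos <- if (!is.null(dataset$scene)) dataset$scene$isos else dataset$isos
  ref <- if (!is.null(dataset$scene)) dataset$scene$reference else dataset$reference
  center0 <- dataset$initialCenter
  stopifnot(is(isos, "StokesMap"), is(ref, "StokesMap"),
            length(center0) == 2L)
  pol0 <- polarizationFromStokes(compensateAnterior(isos, ref, c(0, 0)))
  rc <- rotationCorrection(pol0, center0, annulus, nSegments,
                           minSegFrac = minSegFrac)
  pol1 <- .rotatePol(pol0, rc$rotation)
  c1 <- refineCenter(pol1, center0, annulus, window, nSegments,
                     minSegFrac = minSegFrac)
  center <- c1$center
  offsets <- NULL
  os <- NULL
  for (round in seq_len(maxRounds)) {
    os <- offsetSearch(isos, ref, rc$rotation, center, annulus, offsetGrid,
                       nSegments, minSegFrac)
    c2 <- refineCenter(os$pol, center, annulus, window, nSegments,
                       minSegFrac = minSegFrac)
    done <- !is.null(offsets) && all(os$offsets == offsets) &&
      all(c2$center == center)
    center <- c2$center
    offsets <- os$offsets
    if (done) break
  }
  profile <- mdProfile(os$pol, center, nSegments,
                       minSegFrac = minSegFrac,
                       rotation = os$rotation, offsets = os$offsets)
  list(profile = profile, pol = os$pol, stokes = os$stokes,
       rotation = os$rotation, center = center, offsets = os$offsets)
}

#' Lateral HFL extension from an MD profile
#'
#' Scanning outward from the minimum-MD annulus, the first crossing of the MD
#' above the cut-off (default 0.65, about half the random-axis noise floor)
#' marks the end of the detectable fiber pattern; the crossing eccentricity
#' is interpolated linearly between the mid-radii of the bracketing annuli.
#' Profiles never exceeding the cut-off return the field limit of 14 degrees,
#' profiles never below it return 0; both are flagged.
#'
#' @param profile a \linkS4class{HenleMDProfile}.
#' @param cutoff MD value above which no fiber pattern is assumed.
#' @return extension in degrees, with attribute \code{flag} one of "ok",
#'   "ceiling" (never above cut-off), "no_pattern" (never below).
#' @examples
#' md <- c(NA, rep(0.5, 7), 0.8, rep(1.2, 5))
#' p <- new("HenleMDProfile", md = md, center = c(0, 0), rotation = 0,
#'          offsets = c(0, 0))
#' hflExtension(p)  # crosses 0.65 between 7.5 and 8.5 deg -> 8.0
#' @export
hflExtension <- function(profile, cutoff = 0.65) {
  md <- profile@md
  mids <- (0:13) + 0.5
  def <- which(is.finite(md))
  if (length(def) < 2) stop("need at least two defined annuli")
  imin <- def[which.min(md[def])]
  if (md[imin] > cutoff) {
    out <- 0
    attr(out, "flag") <- "no_pattern"
    return(out)
  }
  below <- imin
  for (k in def[def > imin]) {
    if (md[k] > cutoff) {
      ext <- mids[below] + (cutoff - md[below]) / (md[k] - md[below]) *
        (mids[k] - mids[below])
      attr(ext, "flag") <- "ok"
      return(ext)
    }
    below <- k
  }
  out <- 14
  attr(out, "flag") <- "ceiling"
  out
}

#' Select the best repeat acquisition
#'
#' Given repeated MD profiles of one subject, returns the index of the
#' profile with the lowest mean MD over the annuli from 1 to 8 degrees
#' eccentricity (ties: first). This automatically discards repeats with
#' erroneous segmentation or compensation.
#'
#' @param profiles list of \linkS4class{HenleMDProfile}.
#' @return integer index into \code{profiles}.
#' @export
selectBestRepeat <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  score <- vapply(profiles, function(p) mean(p@md[2:8], na.rm = TRUE),
                  numeric(1))
  which.min(score)
}
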