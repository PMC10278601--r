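## Stokes-vector polarization core.
##
## Measurement frame: the circular input state of the instrument lies along +Q
## of the measured Stokes frame, so an unretarded, polarization-preserving
## sample returns (Q, U, V)/I = (1, 0, 0). A linear retarder with single-pass
## retardance delta (deg) and axis orientation theta (deg) acts as the
## Poincare-sphere rotation about (0, cos 2*theta, sin 2*theta) by 2*delta
## (the factor 2 folds in the double pass of the sample arm; all retardation
## values reported by the package are single-pass-equivalent). Under this
## convention the retardation read-out is literally
## delta = 1/2 * acos(<Q/I>_N) and the axis read-out is
## theta = 1/2 * atan2(<U/I>_N, -<V/I>_N).

# clamp to [-1, 1]; values beyond 1 + tol trigger a warning before clamping
.clamp1 <- function(x, tol = 1e-9) {
  bad <- !is.na(x) & (x > 1 + tol | x < -1 - tol)
  if (any(bad))
    warning(sprintf("%d value(s) clamped to [-1, 1] beyond tolerance %g",
                    sum(bad), tol))
  pmin(pmax(x, -1), 1)
}

# Rodrigues rotation of (Q, U, V) about (0, cos 2*theta, sin 2*theta) by
# 2*delta degrees; delta/theta may be scalars or matrices conforming to Q.
.rotQUV <- function(Q, U, V, deltaDeg, thetaDeg) {
  al <- 2 * deltaDeg * pi / 180
  th2 <- 2 * thetaDeg * pi / 180
  ca <- cos(al); sa <- sin(al)
  c2 <- cos(th2); s2 <- sin(th2)
  kv <- c2 * U + s2 * V
  list(Q = Q * ca + (c2 * V - s2 * U) * sa,
       U = U * ca + s2 * Q * sa + c2 * kv * (1 - ca),
       V = V * ca - c2 * Q * sa + s2 * kv * (1 - ca))
}

# per-pixel normalized Stokes components (q, u, v)/|(q, u, v)| and a defined
# mask; pixels with I <= 0, invalid flag, or vanishing polarized magnitude are
# undefined
.normalizedStokes <- function(s, eps = 1e-12) {
  ok <- s@valid & is.finite(s@I) & s@I > 0
  q <- ifelse(ok, s@Q / s@I, NA_real_)
  u <- ifelse(ok, s@U / s@I, NA_real_)
  v <- ifelse(ok, s@V / s@I, NA_real_)
  mag <- sqrt(q^2 + u^2 + v^2)
  ok <- ok & is.finite(mag) & mag > eps
  list(q = ifelse(ok, q / mag, NA_real_),
       u = ifelse(ok, u / mag, NA_real_),
       v = ifelse(ok, v / mag, NA_real_),
       ok = ok)
}

# windowed sums with cropped borders, window k rows centred at each row
# (for even k the window extends one pixel further down/right)
.winsum1 <- function(m, k) {
  up <- (k - 1L) %/% 2L
  down <- k - 1L - up
  ny <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  r2 <- pmin(seq_len(ny) + down, ny)
  r1 <- pmax(seq_len(ny) - up, 1L)
  cs[r2 + 1L, , drop = FALSE] - cs[r1, , drop = FALSE]
}

.boxSum <- function(m, kernel) {
  t(.winsum1(t(.winsum1(m, kernel[1])), kernel[2]))
}

# masked box mean: mean of x over valid pixels in each (cropped) window;
# windows without any valid pixel give NA
.boxMeanMasked <- function(x, valid, kernel) {
  x0 <- x
  x0[!valid] <- 0
  n <- .boxSum(matrix(as.numeric(valid), nrow(x), ncol(x)), kernel)
  s <- .boxSum(x0, kernel)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

#' Average Stokes vectors over a kernel or an index set
#'
#' Averaging is performed componentwise on (I, Q, U, V) before any conversion
#' to retardation. This is the bias-free alternative to averaging retardation
#' values directly, which are non-negative and therefore acquire an artificial
#' offset in noise.
#'
#' @param s a \linkS4class{StokesMap}.
#' @param kernel integer(2) window size (rows, cols); windows are cropped at
#'   the image border and respect the validity mask. Mutually exclusive with
#'   \code{index}.
#' @param index a logical mask or integer index vector selecting pixels to
#'   pool into a single averaged Stokes vector.
#' @return With \code{kernel}: a smoothed \linkS4class{StokesMap} (pixels whose
#'   window holds no valid pixel become invalid). With \code{index}: a named
#'   numeric (I, Q, U, V), all NA if the selection holds no valid pixel.
#' @export
averageStokes <- function(s, kernel = NULL, index = NULL) {
  stopifnot(is(s, "StokesMap"), is.null(kernel) != is.null(index))
  if (!is.null(kernel)) {
    kernel <- as.integer(kernel)
    stopifnot(length(kernel) == 2L, all(kernel >= 1L))
    comps <- lapply(c("I", "Q", "U", "V"), function(nm)
      .boxMeanMasked(slot(s, nm), s@valid, kernel))
    names(comps) <- c("I", "Q", "U", "V")
    ok <- !is.na(comps$I)
    for (nm in names(comps)) comps[[nm]][!ok] <- 0
    new("StokesMap", I = comps$I, Q = comps$Q, U = comps$U, V = comps$V,
        valid = ok, surface = s@surface, geometry = s@geometry)
  } else {
    sel <- if (is.logical(index)) index & s@valid else {
      m <- matrix(FALSE, nrow(s@I), ncol(s@I))
      m[index] <- TRUE
      m & s@valid
    }
    if (!any(sel))
      return(c(I = NA_real_, Q = NA_real_, U = NA_real_, V = NA_real_))
    c(I = mean(s@I[sel]), Q = mean(s@Q[sel]),
      U = mean(s@U[sel]), V = mean(s@V[sel]))
  }
}

#' Smooth a Stokes map with a windowed mean
#'
#' Componentwise windowed averaging of the Stokes elements (default 9 x 9
#' pixels) respecting the validity mask; border windows are cropped.
#'
#' @param s a \linkS4class{StokesMap}.
#' @param kernel integer(2), window size (rows, cols).
#' @return a smoothed \linkS4class{StokesMap}.
#' @export
smoothStokes <- function(s, kernel = c(9, 9)) {
  averageStokes(s, kernel = kernel)
}

#' Retardation map from Stokes data
#'
#' Applies delta = 1/2 * acos(q_N), where q_N is the Q/I component of the
#' per-pixel normalized Stokes vector. The result lies in [0, 90] degrees.
#' Pixels with vanishing polarized magnitude are returned as NA.
#'
#' @param s a \linkS4class{StokesMap}.
#' @return numeric matrix of retardation in degrees (NA where undefined).
#' @export
retardationFromStokes <- function(s) {
  ns <- .normalizedStokes(s)
  out <- 0.5 * acos(.clamp1(ns$q)) * 180 / pi
  out[!ns$ok] <- NA_real_
  out
}

#' Axis-orientation map from Stokes data
#'
#' Applies theta = 1/2 * atan2(u_N, -v_N) under the single-circular-input
#' convention, wrapped into [-90, 90). Half-turn periodicity is inherent:
#' theta and theta + 180 give identical maps. Pixels whose transverse
#' components (U, V) both vanish have no defined axis and are returned as NA.
#'
#' @param s a \linkS4class{StokesMap}.
#' @param eps transverse-magnitude threshold below which the axis is undefined.
#' @return numeric matrix of axis orientation in degrees (NA where undefined).
#' @export
axisFromStokes <- function(s, eps = 1e-12) {
  ns <- .normalizedStokes(s)
  ok <- ns$ok & sqrt(ns$u^2 + ns$v^2) > eps
  out <- wrapAxis(0.5 * atan2(ns$u, -ns$v) * 180 / pi)
  out[!ok] <- NA_real_
  out
}

#' Extract paired retardation and axis maps
#'
#' @param s a \linkS4class{StokesMap}.
#' @return a \linkS4class{PolarizationMaps}; pixels where either quantity is
#'   undefined are flagged invalid.
#' @export
polarizationFromStokes <- function(s) {
  ret <- retardationFromStokes(s)
  ax <- suppressWarnings(axisFromStokes(s))
  ok <- !is.na(ret) & !is.na(ax)
  ret[!ok] <- 0
  ax[!ok] <- 0
  new("PolarizationMaps", retardation = ret, axis = ax, valid = ok,
      geometry = s@geometry)
}

#' Degree of polarization uniformity (DOPU)
#'
#' DOPU is the length of the kernel-mean of the per-pixel normalized Stokes
#' vectors: 1 where the polarization state is spatially uniform, near 0 in
#' depolarizing tissue such as the RPE. Border kernels are cropped (no
#' padding); the default kernel is 10 x 10 pixels.
#'
#' @param s a \linkS4class{StokesMap}, or a list with matrices I, Q, U, V (and
#'   optionally valid) for raw B-scan slices.
#' @param kernel integer(2), kernel size (rows, cols).
#' @return numeric matrix of DOPU in [0, 1] (NA where the kernel holds no
#'   valid pixel).
#' @export
dopuMap <- function(s, kernel = c(10, 10)) {
  if (is(s, "StokesMap")) {
    ns <- .normalizedStokes(s)
  } else {
    valid <- if (is.null(s$valid)) is.finite(s$I) & s$I > 0 else s$valid
    sm <- new("StokesMap", I = s$I, Q = s$Q, U = s$U, V = s$V,
              valid = valid, surface = "raw",
              geometry = sceneGeometry(gridPx = c(ncol(s$I), nrow(s$I))))
    ns <- .normalizedStokes(sm)
  }
  mq <- .boxMeanMasked(ifelse(ns$ok, ns$q, 0), ns$ok, kernel)
  mu <- .boxMeanMasked(ifelse(ns$ok, ns$u, 0), ns$ok, kernel)
  mv <- .boxMeanMasked(ifelse(ns$ok, ns$v, 0), ns$ok, kernel)
  pmin(sqrt(mq^2 + mu^2 + mv^2), 1)
}

#' Construct a retarder
#'
#' @param retardation single-pass-equivalent retardance in degrees, [0, 180).
#' @param axis axis orientation in degrees, [-90, 90).
#' @return a \linkS4class{Retarder}.
#' @export
retarder <- function(retardation, axis) {
  new("Retarder", retardation = as.numeric(retardation),
      axis = as.numeric(wrapAxis(axis)))
}

#' Apply a retarder to a Stokes map
#'
#' Rotates the polarized components (Q, U, V) of every pixel on the Poincare
#' sphere about the retarder axis by twice the single-pass retardance (double
#' pass folded in); I is unchanged, and the polarized magnitude is conserved.
#' Applying the inverse retarder (same axis, negated retardance) restores the
#' input.
#'
#' @param s a \linkS4class{StokesMap}.
#' @param r a \linkS4class{Retarder}, or numeric(2) (retardation, axis) in
#'   degrees. The retardation may be negative to express an inverse.
#' @return the transformed \linkS4class{StokesMap}.
#' @export
applyRetarder <- function(s, r) {
  stopifnot(is(s, "StokesMap"))
  if (is(r, "Retarder")) {
    d <- r@retardation; a <- r@axis
  } else {
    stopifnot(is.numeric(r), length(r) == 2L)
    d <- r[1]; a <- r[2]
  }
  rot <- .rotQUV(s@Q, s@U, s@V, d, a)
  initialize(s, Q = rot$Q, U = rot$U, V = rot$V)
}

#' Compensate anterior-segment birefringence
#'
#' Per pixel, estimates the anterior retarder (cornea + RNFL surrogate) from
#' the Stokes state measured at a reference surface anterior to the target
#' (the known circular input state makes the retarder identifiable from a
#' single measurement), optionally adds global offsets (d retardation, d axis)
#' to the estimate, and applies the inverse rotation to the target map. With
#' an exact reference and zero offsets this recovers the sample polarization
#' exactly.
#'
#' @param target \linkS4class{StokesMap} at the layer of interest (IS/OS).
#' @param reference \linkS4class{StokesMap} at the anterior reference surface.
#' @param offsets numeric(2), degrees added to the estimated anterior
#'   (retardation, axis); the correction grid search explores [-5, 5].
#' @return the compensated \linkS4class{StokesMap}; pixels with an invalid
#'   reference become invalid.
#' @export
compensateAnterior <- function(target, reference, offsets = c(0, 0)) {
  stopifnot(is(target, "StokesMap"), is(reference, "StokesMap"),
            identical(dim(target@I), dim(reference@I)),
            length(offsets) == 2L)
  ns <- .normalizedStokes(reference)
  dA <- 0.5 * acos(.clamp1(ns$q)) * 180 / pi + offsets[1]
  tA <- 0.5 * atan2(ns$u, -ns$v) * 180 / pi + offsets[2]
  ok <- ns$ok & target@valid
  dA[!ok] <- 0
  tA[!ok] <- 0
  rot <- .rotQUV(target@Q, target@U, target@V, -dA, tA)
  initialize(target, Q = rot$Q, U = rot$U, V = rot$V, valid = ok)
}

#' Convert retardation from degrees to nanometres
#'
#' delta / 360 * lambda: at 860 nm, 9 degrees correspond to 21.5 nm.
#'
#' @param delta retardation in degrees (>= 0).
#' @param wavelengthNm wavelength in nm.
#' @return retardance in nm.
#' @examples
#' retardationDegToNm(9, 860)
#' @export
retardationDegToNm <- function(delta, wavelengthNm = 860) {
  if (any(delta < 0, na.rm = TRUE))
    stop("retardation must be non-negative")
  delta / 360 * wavelengthNm
}
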