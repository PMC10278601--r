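## Synthetic PS-OCT generator: ground-truthed en-face Stokes scenes and small
## layered volumes exhibiting the structure the analysis assumes (radial Henle
## axis pattern, donut-shaped retardation, anterior-retarder corruption,
## additive Stokes noise at a configurable SNR).

.configError <- function(msg) {
  stop(errorCondition(msg, class = c("henleConfigError", "error", "condition")))
}

# run expr with a private RNG stream seeded from `seed`, restoring the caller's
# RNG state afterwards so generators are deterministic without side effects
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# smooth, compactly supported radial retardation profile: 0 at the centre,
# peak at peakEcc, back to 0 at extension (raised-cosine on both flanks)
.radialRetardation <- function(ecc, peak, peakEcc, extension) {
  out <- numeric(length(ecc))
  rising <- ecc <= peakEcc
  falling <- ecc > peakEcc & ecc < extension
  out[rising] <- 0.5 * (1 - cos(pi * ecc[rising] / peakEcc))
  out[falling] <- 0.5 * (1 + cos(pi * (ecc[falling] - peakEcc) /
                                   (extension - peakEcc)))
  dim(out) <- dim(ecc)
  peak * out
}

# default per-field sampling ranges; length-1 entries pin a value, length-2
# entries are uniform ranges
.truthDefaults <- function(group = c("healthy", "glaucoma"),
                           geom = sceneGeometry()) {
  group <- match.arg(group)
  ppd <- pxPerDeg(geom)
  cx <- geom@gridPx[1] / 2
  cy <- geom@gridPx[2] / 2
  list(
    foveaCenterX = cx + c(-1, 1) * ppd[["x"]],
    foveaCenterY = cy + c(-1, 1) * ppd[["y"]],
    hflExtension = if (group == "healthy") c(5, 12) else c(4.5, 11.5),
    peakRetardation = if (group == "healthy") c(9, 11) else c(8, 10.5),
    peakEccentricity = c(1.8, 2.2),
    asymmetryRatio = c(1, 1.3),
    anteriorRetardation = c(10, 35),
    anteriorAxis = c(-90, 89.99),
    snrDb = c(12, 25),
    rotationOffset = c(-90, 90)
  )
}

#' Draw a ground truth for one synthetic scene
#'
#' Samples every field of \linkS4class{HenleGroundTruth} uniformly from
#' configurable ranges. Defaults follow the study conditions of the analysis:
#' healthy lateral extensions between 5 and 12 degrees, a donut retardation
#' peak of 9-11 degrees near 2 degrees eccentricity, a slight nasal-temporal
#' asymmetry (ratio up to 1.3), and an anterior retarder standing in for
#' cornea plus RNFL.
#'
#' @param config named list overriding default ranges; a length-1 entry pins
#'   the value, a length-2 entry is a uniform sampling range. Names as in
#'   \code{\link{sceneGeometry}} truth fields, e.g. \code{hflExtension},
#'   \code{snrDb}.
#' @param seed integer; fixed seed gives an identical truth.
#' @param group "healthy" or "glaucoma"; selects the default parameter ranges.
#' @param geom a \linkS4class{SceneGeometry}.
#' @return a \linkS4class{HenleGroundTruth}.
#' @examples
#' makeTruth(seed = 1)
#' makeTruth(config = list(hflExtension = c(5, 12)), seed = 2)
#' @export
makeTruth <- function(config = list(), seed, group = "healthy",
                      geom = sceneGeometry()) {
  defaults <- .truthDefaults(group, geom)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    .configError(paste("unknown truth parameter(s):",
                       paste(unknown, collapse = ", ")))
  ranges <- utils::modifyList(defaults, config)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || !(length(r) %in% 1:2) || any(is.na(r)) ||
        (length(r) == 2L && r[2] < r[1]) ||
        (any(!is.finite(r)) && nm != "snrDb"))
      .configError(sprintf("invalid range for '%s'", nm))
  }
  bounds <- list(hflExtension = c(1e-6, 14), peakRetardation = c(0, 45),
                 asymmetryRatio = c(1, Inf), anteriorAxis = c(-90, 90),
                 anteriorRetardation = c(0, 90))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (any(ranges[[nm]] < b[1]) || any(ranges[[nm]] > b[2]))
      .configError(sprintf("range for '%s' outside [%g, %g]", nm, b[1], b[2]))
  }
  .withSeed(seed, {
    draw <- function(nm) {
      r <- ranges[[nm]]
      if (length(r) == 1L || r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
    }
    ext <- draw("hflExtension")
    pe <- min(draw("peakEccentricity"), 0.9 * ext)
    new("HenleGroundTruth",
        foveaCenter = c(draw("foveaCenterX"), draw("foveaCenterY")),
        hflExtension = ext,
        peakRetardation = draw("peakRetardation"),
        peakEccentricity = pe,
        asymmetryRatio = draw("asymmetryRatio"),
        anteriorRetardation = draw("anteriorRetardation"),
        anteriorAxis = wrapAxis(draw("anteriorAxis")),
        snrDb = draw("snrDb"),
        rotationOffset = draw("rotationOffset"),
        seed = as.integer(seed))
  })
}

# noise standard deviation per Stokes component from the SNR convention:
# snrDb = 10 * log10(I / threshold) with threshold = 7 * sigma
.noiseSigma <- function(snrDb, intensity = 1) {
  if (!is.finite(snrDb)) 0 else intensity / (7 * 10^(snrDb / 10))
}

.stokesMap <- function(I, Q, U, V, valid, surface, geom) {
  new("StokesMap", I = I, Q = Q, U = U, V = V, valid = valid,
      surface = surface, geometry = geom)
}

#' Render synthetic en-face Stokes maps
#'
#' Forward model: Henle fibers emerge radially from the fovea, so the
#' ground-truth slow-axis orientation at a pixel equals its azimuth about the
#' fovea centre mapped into [-90, 90) (anchored so that azimuth 0 carries axis
#' -90), plus a global rotation offset; the ground-truth retardation follows a
#' smooth radial raised-cosine bump peaking at \code{peakEccentricity} and
#' vanishing beyond \code{hflExtension}, with the horizontal extent widened by
#' \code{asymmetryRatio}. Both the IS/OS map and the anterior reference map
#' are corrupted by the same anterior retarder on the Poincare sphere, and
#' independent Gaussian noise is added to every Stokes component according to
#' \code{snrDb} (Inf disables noise). The validity mask marks pixels whose
#' intensity falls below the noise threshold (7 sigma).
#'
#' @param truth a \linkS4class{HenleGroundTruth}.
#' @param geom a \linkS4class{SceneGeometry}.
#' @param perturbReference numeric(2), degrees added to the (retardation,
#'   axis) of the anterior retarder as seen by the reference surface only;
#'   models an imprecise reference measurement, recovered downstream by the
#'   compensation-offset grid search.
#' @return list with elements \code{isos} and \code{reference}
#'   (\linkS4class{StokesMap}s), the uncorrupted ground-truth fields
#'   \code{truthRetardation} and \code{truthAxis} (matrices, degrees),
#'   \code{noiseSigma}, \code{threshold}, \code{truth} and \code{geometry}.
#' @export
renderEnface <- function(truth, geom = sceneGeometry(),
                         perturbReference = c(0, 0)) {
  stopifnot(is(truth, "HenleGroundTruth"))
  grid <- degreeGrid(geom, truth@foveaCenter, truth@asymmetryRatio)
  deltaS <- .radialRetardation(grid$eccEff, truth@peakRetardation,
                               truth@peakEccentricity, truth@hflExtension)
  thetaS <- wrapAxis(grid$phi - 90 + truth@rotationOffset)
  I0 <- 1
  d2 <- 2 * deltaS * pi / 180
  t2 <- 2 * thetaS * pi / 180
  sample <- list(Q = cos(d2), U = sin(d2) * sin(t2), V = -sin(d2) * cos(t2))
  isos <- .rotQUV(sample$Q, sample$U, sample$V,
                  truth@anteriorRetardation, truth@anteriorAxis)
  one <- matrix(1, geom@gridPx[2], geom@gridPx[1])
  zero <- matrix(0, geom@gridPx[2], geom@gridPx[1])
  ref <- .rotQUV(one, zero, zero,
                 truth@anteriorRetardation + perturbReference[1],
                 wrapAxis(truth@anteriorAxis + perturbReference[2]))
  sigma <- .noiseSigma(truth@snrDb, I0)
  threshold <- 7 * sigma
  maps <- .withSeed(truth@seed + 104729, {
    addNoise <- function(m) {
      Iobs <- I0 * one + if (sigma > 0) matrix(stats::rnorm(length(one), 0, sigma),
                                               nrow(one)) else 0
      noisy <- lapply(m, function(x) {
        I0 * x + if (sigma > 0) matrix(stats::rnorm(length(x), 0, sigma),
                                       nrow(x)) else 0
      })
      valid <- if (sigma > 0) Iobs > threshold else one > 0
      Iobs[valid & Iobs < 0] <- 0   # cannot happen for threshold > 0; guard
      list(I = Iobs, Q = noisy$Q, U = noisy$U, V = noisy$V, valid = valid)
    }
    list(isos = addNoise(isos), ref = addNoise(ref))
  })
  list(isos = .stokesMap(maps$isos$I, maps$isos$Q, maps$isos$U, maps$isos$V,
                         maps$isos$valid, "ISOS", geom),
       reference = .stokesMap(maps$ref$I, maps$ref$Q, maps$ref$U, maps$ref$V,
                              maps$ref$valid, "reference", geom),
       truthRetardation = deltaS, truthAxis = thetaS,
       noiseSigma = sigma, threshold = threshold,
       truth = truth, geometry = geom)
}

#' Render a small layered PS-OCT volume
#'
#' Builds a mini volume [depth, x, B-scan] containing, from top to bottom: a
#' dim polarization-preserving inner-retina band, a brighter reference plane
#' (the surrogate for the brightest pixel between RNFL-GCL and INL-OPL), a
#' bright polarization-preserving IS/OS band carrying the Henle-corrupted
#' signal, a bright depolarizing RPE band (random polarization states), and a
#' background noise floor whose magnitude decays linearly with depth. An
#' approximate IS/OS segmentation line, jittered by up to \code{jitterPx}
#' pixels, is returned alongside the exact one.
#'
#' @param truth a \linkS4class{HenleGroundTruth}.
#' @param geom a \linkS4class{SceneGeometry}; its grid provides the lateral
#'   (x) and B-scan (y) sampling of the volume.
#' @param nBscans number of B-scans (>= 8); must match \code{geom@gridPx[2]}.
#' @param depthPx A-scan depth in pixels (>= 64).
#' @param jitterPx maximum absolute segmentation jitter in pixels.
#' @param perturbReference as in \code{\link{renderEnface}}.
#' @return list with \code{volume} (list of arrays I, Q, U, V), matrices
#'   \code{isosTrue} and \code{isosInitial} (depth indices, [B-scan, x]),
#'   \code{refRange} (depth rows enclosing the reference plane), layer row
#'   indices, \code{noiseSigma}, \code{truth}, \code{geometry}.
#' @export
renderVolume <- function(truth, geom = sceneGeometry(gridPx = c(96, 24)),
                         nBscans = geom@gridPx[2], depthPx = 96,
                         jitterPx = 3, perturbReference = c(0, 0)) {
  if (nBscans < 8 || depthPx < 64)
    .configError("volume requires nBscans >= 8 and depthPx >= 64")
  if (nBscans != geom@gridPx[2])
    geom <- sceneGeometry(geom@fieldDeg, c(geom@gridPx[1], nBscans),
                          geom@mmPerDeg, geom@wavelengthNm)
  nx <- geom@gridPx[1]
  nb <- geom@gridPx[2]
  D <- as.integer(depthPx)

  grid <- degreeGrid(geom, truth@foveaCenter, truth@asymmetryRatio)
  deltaS <- .radialRetardation(grid$eccEff, truth@peakRetardation,
                               truth@peakEccentricity, truth@hflExtension)
  thetaS <- wrapAxis(grid$phi - 90 + truth@rotationOffset)
  d2 <- 2 * deltaS * pi / 180
  t2 <- 2 * thetaS * pi / 180
  sQ <- cos(d2); sU <- sin(d2) * sin(t2); sV <- -sin(d2) * cos(t2)
  isosState <- .rotQUV(sQ, sU, sV, truth@anteriorRetardation, truth@anteriorAxis)
  refState <- .rotQUV(matrix(1, nb, nx), matrix(0, nb, nx), matrix(0, nb, nx),
                      truth@anteriorRetardation + perturbReference[1],
                      wrapAxis(truth@anteriorAxis + perturbReference[2]))

  # bright structures must stay within the darkest-80% assumption of the
  # threshold estimator, i.e. below ~20% of the pixels
  innerRows <- seq.int(round(0.20 * D), round(0.27 * D))
  zRef <- round(0.38 * D)
  refRange <- c(round(0.34 * D), round(0.44 * D))
  zIsos <- round(0.62 * D)
  isosRows <- (zIsos - 1L):(zIsos + 1L)
  rpeRows <- (zIsos + 6L):(zIsos + 8L)
  iInner <- 0.3; iRef <- 0.8; iIsos <- 1.0; iRpe <- 0.85

  sigma <- .noiseSigma(truth@snrDb, iIsos)
  bg0 <- max(sigma, 1e-3)

  .withSeed(truth@seed + 224737, {
    I <- array(0, c(D, nx, nb)); Q <- I; U <- I; V <- I
    # background: |N(0, sigma_bg(z))| on I, N(0, sigma_bg(z)) on Q, U, V,
    # with sigma_bg decaying linearly in depth
    decay <- 1 - 0.4 * (seq_len(D) - 1) / (D - 1)
    n <- nx * nb
    for (z in seq_len(D)) {
      s <- bg0 * decay[z]
      I[z, , ] <- abs(stats::rnorm(n, 0, s))
      Q[z, , ] <- stats::rnorm(n, 0, s)
      U[z, , ] <- stats::rnorm(n, 0, s)
      V[z, , ] <- stats::rnorm(n, 0, s)
    }
    put <- function(rows, intensity, q, u, v) {
      # q, u, v: normalized state matrices [nb, nx] (or scalars); transpose to
      # the [x, b] layout of the volume slices
      for (z in rows) {
        I[z, , ] <<- intensity + if (sigma > 0)
          matrix(stats::rnorm(n, 0, sigma), nx) else 0
        Q[z, , ] <<- intensity * t(q) + if (sigma > 0)
          matrix(stats::rnorm(n, 0, sigma), nx) else 0
        U[z, , ] <<- intensity * t(u) + if (sigma > 0)
          matrix(stats::rnorm(n, 0, sigma), nx) else 0
        V[z, , ] <<- intensity * t(v) + if (sigma > 0)
          matrix(stats::rnorm(n, 0, sigma), nx) else 0
      }
    }
    ones <- matrix(1, nb, nx); zeros <- matrix(0, nb, nx)
    anteriorInput <- .rotQUV(ones, zeros, zeros,
                             truth@anteriorRetardation, truth@anteriorAxis)
    put(innerRows, iInner, anteriorInput$Q, anteriorInput$U, anteriorInput$V)
    put(zRef, iRef, refState$Q, refState$U, refState$V)
    # IS/OS: peaked intensity profile so the brightest pixel marks the centre
    for (j in seq_along(isosRows))
      put(isosRows[j], iIsos * c(0.9, 1, 0.9)[j],
          isosState$Q, isosState$U, isosState$V)
    # depolarizing RPE: independent random unit Stokes directions per pixel
    for (z in rpeRows) {
      g1 <- stats::rnorm(n); g2 <- stats::rnorm(n); g3 <- stats::rnorm(n)
      mag <- sqrt(g1^2 + g2^2 + g3^2)
      I[z, , ] <- iRpe + if (sigma > 0) matrix(stats::rnorm(n, 0, sigma), nx) else 0
      Q[z, , ] <- iRpe * matrix(g1 / mag, nx)
      U[z, , ] <- iRpe * matrix(g2 / mag, nx)
      V[z, , ] <- iRpe * matrix(g3 / mag, nx)
    }
    isosTrue <- matrix(zIsos, nb, nx)
    jit <- if (jitterPx > 0)
      matrix(sample(seq.int(-jitterPx, jitterPx), nb * nx, replace = TRUE), nb)
    else matrix(0L, nb, nx)
    list(volume = list(I = I, Q = Q, U = U, V = V),
         isosTrue = isosTrue, isosInitial = isosTrue + jit,
         refRange = refRange, innerRows = innerRows, isosRows = isosRows,
         rpeRows = rpeRows, noiseSigma = sigma,
         truth = truth, geometry = geom)
  })
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws per-subject ground truths with group-dependent parameter ranges,
#' renders the en-face scene, and attaches the observation-side unknowns the
#' correction pipeline is expected to undo: an initial fovea-centre estimate
#' offset by up to \code{centerOffsetPx} pixels per coordinate, and an integer
#' perturbation of the anterior reference within \code{perturbMaxDeg} degrees.
#' Ages are drawn per group; unless the config pins \code{snrDb}, SNR is
#' coupled negatively to age (older subjects image with lower SNR).
#'
#' @param n number of subjects.
#' @param group "healthy" or "glaucoma".
#' @param seed integer seed for the whole cohort.
#' @param geom a \linkS4class{SceneGeometry}.
#' @param config truth-range overrides passed to \code{\link{makeTruth}}.
#' @param centerOffsetPx max absolute initial-centre offset per coordinate.
#' @param perturbMaxDeg max absolute reference perturbation (integer degrees).
#' @return list of subjects; each holds \code{id}, \code{group}, \code{age},
#'   \code{truth}, \code{scene} (see \code{\link{renderEnface}}),
#'   \code{initialCenter} (px) and \code{perturbation} (deg).
#' @export
simulateCohort <- function(n, group = c("healthy", "glaucoma"), seed,
                           geom = sceneGeometry(), config = list(),
                           centerOffsetPx = 15, perturbMaxDeg = 3) {
  group <- match.arg(group)
  lapply(seq_len(n), function(i) {
    si <- (as.integer(seed) + 9973L * i) %% 2147483647L
    meta <- .withSeed(si + 7L, {
      age <- if (group == "healthy") stats::rnorm(1, 60.3, 8.7)
             else stats::rnorm(1, 63.2, 9.5)
      age <- min(max(age, 21), 79)
      off <- sample(seq.int(-centerOffsetPx, centerOffsetPx), 2, replace = TRUE)
      per <- sample(seq.int(-perturbMaxDeg, perturbMaxDeg), 2, replace = TRUE)
      snr <- min(max(28 - 0.18 * age + stats::rnorm(1, 0, 2), 8), 28)
      list(age = age, off = off, per = per, snr = snr)
    })
    cfg <- config
    if (is.null(cfg$snrDb)) cfg$snrDb <- meta$snr
    truth <- makeTruth(cfg, seed = si, group = group, geom = geom)
    scene <- renderEnface(truth, geom, perturbReference = meta$per)
    list(id = sprintf("%s%03d", substr(group, 1, 1), i), group = group,
         age = meta$age, truth = truth, scene = scene,
         initialCenter = truth@foveaCenter + meta$off,
         perturbation = meta$per)
  })
}
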