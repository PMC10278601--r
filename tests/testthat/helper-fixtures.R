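# Shared fixture builders. Everything is generated in code at test time.

# a clean, fully pinned truth: no anterior corruption, no rotation, no noise
cleanTruth <- function(seed = 1, geom = sceneGeometry(), extension = 10,
                       peak = 10, peakEcc = 2, asym = 1, snrDb = Inf,
                       anterior = c(0, 0), rotation = 0,
                       center = geom@gridPx / 2) {
  makeTruth(config = list(anteriorRetardation = anterior[1],
                          anteriorAxis = anterior[2], snrDb = snrDb,
                          rotationOffset = rotation, hflExtension = extension,
                          peakRetardation = peak, peakEccentricity = peakEcc,
                          asymmetryRatio = asym,
                          foveaCenterX = center[1], foveaCenterY = center[2]),
            seed = seed, geom = geom)
}

# half-resolution geometry for cheaper end-to-end runs
halfGeometry <- function() sceneGeometry(gridPx = c(512, 125))

# a uniform StokesMap with a single polarization state
uniformStokes <- function(state, ny = 20, nx = 30, I = 1,
                          geom = sceneGeometry(gridPx = c(nx, ny))) {
  m <- function(v) matrix(v, ny, nx)
  new("StokesMap", I = m(I), Q = m(state[1] * I), U = m(state[2] * I),
      V = m(state[3] * I), valid = matrix(TRUE, ny, nx),
      surface = "test", geometry = geom)
}

# independent naive reference implementation of the MD statistic:
# plain double loop over pixels and segments, no shared code with the package
naiveMD <- function(axis, valid, geom, center, rin, rout, nseg = 360,
                    minFrac = 0.5) {
  ny <- nrow(axis); nx <- ncol(axis)
  ppx <- geom@gridPx[1] / geom@fieldDeg[1]
  ppy <- geom@gridPx[2] / geom@fieldDeg[2]
  cx <- (center[1] - 0.5) / ppx
  cy <- (center[2] - 0.5) / ppy
  sumRe <- numeric(nseg); sumIm <- numeric(nseg); n <- integer(nseg)
  for (r in seq_len(ny)) {
    for (c in seq_len(nx)) {
      if (!valid[r, c] || !is.finite(axis[r, c])) next
      dx <- (c - 0.5) / ppx - cx
      dyup <- cy - (r - 0.5) / ppy
      ecc <- sqrt(dx^2 + dyup^2)
      if (ecc < rin || ecc >= rout) next
      phi <- (atan2(-dx, dyup) * 180 / pi) %% 360
      s <- min(floor(phi * nseg / 360) + 1, nseg)
      z <- exp(2i * axis[r, c] * pi / 180)
      sumRe[s] <- sumRe[s] + Re(z)
      sumIm[s] <- sumIm[s] + Im(z)
      n[s] <- n[s] + 1L
    }
  }
  ds <- c()
  for (s in seq_len(nseg)) {
    if (n[s] == 0) next
    phiC <- (s - 0.5) * 360 / nseg
    thI <- (phiC %% 180) - 90
    zi <- exp(2i * thI * pi / 180)
    ds <- c(ds, abs(sumRe[s] / n[s] - Re(zi)) + abs(sumIm[s] / n[s] - Im(zi)))
  }
  if (length(ds) < minFrac * nseg) return(NA_real_)
  mean(ds)
}

# an axis map carrying the exact ideal pattern at segment resolution
idealAxisMap <- function(geom, center, nseg = 360) {
  grid <- degreeGrid(geom, center)
  segCenter <- (floor(grid$phi * nseg / 360) + 0.5) * 360 / nseg
  idealAxis(segCenter)
}
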