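test_that("the ideal pattern anchors axis -90 at azimuth 0 and repeats every half turn", {
  expect_equal(idealAxis(0), -90)
  expect_equal(idealAxis(90), 0)
  expect_equal(idealAxis(180), -90)
  expect_equal(idealPattern(0), idealPattern(180))
  expect_equal(idealPattern(37.5), idealPattern(217.5))
  # two full oscillations of Re Z over a full turn
  phi <- seq(0, 359.5, by = 0.5)
  re <- Re(idealPattern(phi))
  sign_changes <- sum(diff(sign(re)) != 0)
  expect_equal(sign_changes, 4)  # cos crosses zero 4 times in two periods
})

test_that("axis-to-complex doubling puts axes on the unit circle with vanishing random mean", {
  expect_equal(axisToComplex(0), 1 + 0i)
  expect_equal(axisToComplex(-90), as.complex(-1), tolerance = 1e-12)
  expect_equal(axisToComplex(45), 1i, tolerance = 1e-12)
  expect_true(all(abs(Mod(axisToComplex(runif(100, -90, 90))) - 1) < 1e-12))
  set.seed(13)
  z <- axisToComplex(runif(2e5, -90, 90))
  expect_lt(Mod(mean(z)), 0.01)
})

test_that("computeMD agrees with the naive double-loop reference to 1e-12", {
  geom <- sceneGeometry(fieldDeg = c(8, 8), gridPx = c(32, 32))
  set.seed(14)
  for (rep in 1:4) {
    ax <- matrix(runif(32 * 32, -90, 90), 32, 32)
    valid <- matrix(runif(32 * 32) > 0.1, 32, 32)
    center <- c(16 + sample(-2:2, 1), 16 + sample(-2:2, 1))
    for (ann in list(c(1, 2), c(2, 3))) {
      got <- computeMD(ax, center, ann, valid = valid, geometry = geom,
                       nSegments = 36L, minSegFrac = 0.1)
      want <- naiveMD(ax, valid, geom, center, ann[1], ann[2], nseg = 36,
                      minFrac = 0.1)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("MD is 0 on the exact ideal pattern and ~4/pi on random axes", {
  geom <- halfGeometry()
  center <- c(256, 62)
  ax <- idealAxisMap(geom, center)
  md <- computeMD(ax, center, c(1, 2), geometry = geom)
  expect_lt(md, 1e-9)
  set.seed(15)
  rnd <- matrix(runif(prod(geom@gridPx), -90, 90), geom@gridPx[2])
  mdr <- computeMD(rnd, center, c(3, 4), geometry = geom)
  expect_equal(mdr, 4 / pi, tolerance = 0.05)
})

test_that("MD of a constant axis map equals the direct-summation closed form", {
  geom <- halfGeometry()
  center <- c(256, 62)
  ax <- matrix(0, geom@gridPx[2], geom@gridPx[1])
  got <- computeMD(ax, center, c(2, 3), geometry = geom)
  # every populated segment holds Z = 1 exactly, so the MD is the mean of
  # |1 - cos(2 theta_ideal)| + |sin(2 theta_ideal)| over those segments
  phi <- (1:360 - 0.5)
  zi <- exp(2i * idealAxis(phi) * pi / 180)
  n <- azimuthalProfile(ax, center, c(2, 3), geometry = geom)$n
  want <- mean((abs(1 - Re(zi)) + abs(0 - Im(zi)))[n > 0])
  expect_equal(got, want, tolerance = 1e-9)
  # on the infinite-segment limit the closed form is 1 + 2/pi
  expect_equal(mean(abs(1 - Re(zi)) + abs(0 - Im(zi))), 1 + 2 / pi,
               tolerance = 1e-4)
})

test_that("MD is gauge invariant: shifting axes and rotating back changes nothing", {
  geom <- halfGeometry()
  center <- c(256, 62)
  set.seed(16)
  ax <- matrix(runif(prod(geom@gridPx), -90, 90), geom@gridPx[2])
  base <- computeMD(ax, center, c(2, 3), geometry = geom)
  for (shift in c(13, 45, 90)) {
    pol <- new("PolarizationMaps",
               retardation = matrix(10, geom@gridPx[2], geom@gridPx[1]),
               axis = wrapAxis(ax + shift),
               valid = matrix(TRUE, geom@gridPx[2], geom@gridPx[1]),
               geometry = geom)
    undone <- HenlePS:::.rotatePol(pol, -shift)
    expect_equal(computeMD(undone, center, c(2, 3)), base, tolerance = 1e-12)
  }
})

test_that("rotation correction recovers an injected rotation offset", {
  geom <- halfGeometry()
  for (rot in c(25, 0, -60)) {
    tr <- cleanTruth(seed = 17, geom = geom, rotation = rot, snrDb = 25)
    sc <- renderEnface(tr, geom)
    pol <- polarizationFromStokes(sc$isos)
    rc <- rotationCorrection(pol, tr@foveaCenter)
    expect_equal(wrapAxis(rc$rotation + rot), 0, tolerance = 1)
    # the chosen rotation is at least as good as every integer candidate
    prof <- azimuthalProfile(pol, tr@foveaCenter)
    ok <- prof$n > 0
    zb <- complex(real = prof$re[ok], imaginary = prof$im[ok])
    zi <- idealPattern(prof$phi[ok])
    sweep <- vapply(0:179, function(r) {
      z <- zb * exp(2i * r * pi / 180)
      mean(abs(Re(z) - Re(zi)) + abs(Im(z) - Im(zi)))
    }, numeric(1))
    expect_lte(rc$md, min(sweep) + 1e-12)
  }
})

test_that("centre refinement finds the fovea and never increases the MD", {
  geom <- halfGeometry()
  tr <- cleanTruth(seed = 18, geom = geom, snrDb = 20)
  sc <- renderEnface(tr, geom)
  pol <- polarizationFromStokes(sc$isos)
  init <- tr@foveaCenter + c(8, -6)
  rc <- refineCenter(pol, init)
  expect_lte(max(abs(rc$center - tr@foveaCenter)), 2)
  expect_lte(rc$md, computeMD(pol, round(init)) + 1e-12)
  # starting at the truth (pinned to a pixel) on clean data: immediate fixed point
  tr0 <- cleanTruth(seed = 18, geom = geom, center = c(256, 62))
  sc0 <- renderEnface(tr0, geom)
  pol0 <- polarizationFromStokes(sc0$isos)
  rc0 <- refineCenter(pol0, c(256, 62))
  expect_true(rc0$converged)
  expect_equal(rc0$center, c(256, 62))
  expect_lte(rc0$iterations, 2)
})

test_that("offset search recovers injected reference perturbations on the grid", {
  geom <- halfGeometry()
  tr <- cleanTruth(seed = 19, geom = geom, anterior = c(20, 35), snrDb = 30)
  sc <- renderEnface(tr, geom, perturbReference = c(3, -2))
  os <- offsetSearch(sc$isos, sc$reference, 0, tr@foveaCenter)
  expect_equal(os$offsets, c(-3, 2))
  # unperturbed reference: argmin at (0, 0)
  sc0 <- renderEnface(tr, geom)
  os0 <- offsetSearch(sc0$isos, sc0$reference, 0, tr@foveaCenter)
  expect_equal(os0$offsets, c(0, 0))
  # minimization: MD at the argmin never exceeds MD at (0, 0)
  osz <- offsetSearch(sc$isos, sc$reference, 0, tr@foveaCenter,
                      offsetGrid = 0)
  expect_lte(os$md, osz$md)
})

test_that("full correction separates pattern from noise across annuli", {
  geom <- sceneGeometry()
  tr <- cleanTruth(seed = 20, geom = geom, extension = 12, snrDb = 22,
                   anterior = c(25, -20), rotation = 40)
  sc <- renderEnface(tr, geom, perturbReference = c(-2, 1))
  fc <- fullCorrection(list(scene = sc,
                            initialCenter = tr@foveaCenter + c(10, -8)))
  md <- mdValues(fc$profile)
  # extension 12: low MD through the 11-12 deg annulus, noise beyond
  expect_true(all(md[3:12] < 0.65))
  expect_true(all(md[13:14] > 0.65))
  # the central disk has elevated MD relative to the 1-2 deg annulus
  expect_gt(md[1], md[2])
  ext <- hflExtension(fc$profile)
  expect_equal(as.numeric(ext), 12, tolerance = 1)
})

test_that("pure noise yields the 1.3 noise floor everywhere and no extension", {
  geom <- halfGeometry()
  tr <- cleanTruth(seed = 21, geom = geom, peak = 0, peakEcc = 2,
                   extension = 10, snrDb = 10)
  sc <- renderEnface(tr, geom)
  pol <- polarizationFromStokes(sc$isos)
  prof <- mdProfile(pol, tr@foveaCenter)
  expect_equal(mean(mdValues(prof), na.rm = TRUE), 4 / pi, tolerance = 0.06)
  ext <- hflExtension(prof)
  expect_equal(as.numeric(ext), 0)
  expect_equal(attr(ext, "flag"), "no_pattern")
})

test_that("expected MD degrades monotonically as SNR drops", {
  geom <- halfGeometry()
  levels <- c(25, 12, 6, 3)
  mds <- vapply(levels, function(db) {
    tr <- cleanTruth(seed = 22, geom = geom, snrDb = db)
    sc <- renderEnface(tr, geom)
    pol <- polarizationFromStokes(sc$isos)
    mean(mdValues(mdProfile(pol, tr@foveaCenter))[3:9], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mds) > 0))
})

test_that("extension interpolates the cut-off crossing between annulus mid-radii", {
  mk <- function(md) new("HenleMDProfile", md = md, center = c(0, 0),
                         rotation = 0, offsets = c(0, 0))
  md <- c(1, rep(0.5, 7), 0.8, rep(1.2, 5))
  expect_equal(as.numeric(hflExtension(mk(md))), 8)  # 7.5 + 0.15/0.3
  allhi <- mk(rep(1.3, 14))
  expect_equal(as.numeric(hflExtension(allhi)), 0)
  expect_equal(attr(hflExtension(allhi), "flag"), "no_pattern")
  alllo <- mk(rep(0.1, 14))
  expect_equal(as.numeric(hflExtension(alllo)), 14)
  expect_equal(attr(hflExtension(alllo), "flag"), "ceiling")
  expect_error(hflExtension(mk(c(0.2, rep(NA, 13)))))
})

test_that("the best repeat is the one with minimal MD between 1 and 8 degrees", {
  mk <- function(md) new("HenleMDProfile", md = md, center = c(0, 0),
                         rotation = 0, offsets = c(0, 0))
  same <- mk(rep(0.5, 14))
  expect_equal(selectBestRepeat(list(same, same, same)), 1)
  lower <- mk(rep(0.3, 14))
  expect_equal(selectBestRepeat(list(same, lower, same)), 2)
  # over seeded trials, the highest-SNR repeat is selected almost always
  geom <- halfGeometry()
  wins <- 0L
  trials <- 12
  for (k in seq_len(trials)) {
    profs <- lapply(c(10, 20, 30), function(db) {
      tr <- cleanTruth(seed = 100 + k, geom = geom, snrDb = db)
      sc <- renderEnface(tr, geom)
      mdProfile(polarizationFromStokes(sc$isos), tr@foveaCenter)
    })
    if (selectBestRepeat(profs) == 3) wins <- wins + 1L
  }
  expect_gte(wins / trials, 0.9)
})
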