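test_that("threshold profile matches a brute-force sort-and-slice oracle", {
  set.seed(9)
  b <- matrix(rnorm(1e6, 10, 2), 1000, 1000)
  tp <- thresholdProfile(b)
  # independent oracle: sort, slice the darkest 80%, mean + 7 sd
  v <- sort(as.vector(b))
  dark <- v[1:floor(0.8 * length(v))]
  expect_equal(tp@base, mean(dark) + 7 * sd(dark), tolerance = 1e-12)
  expect_lt(abs(tp@base - (mean(dark) + 7 * sd(dark))) / tp@base, 0.01)
  # row-k threshold formula is exact
  k <- 57
  expect_equal(thresholdAt(tp, k), tp@base - (k - 1) * 8e-4 * sd(dark),
               tolerance = 1e-12)
  # threshold decreases strictly with depth
  expect_true(all(diff(thresholdAt(tp, 1:1000)) < 0))
})

test_that("degenerate B-scans give base 0 or a zero-sd warning", {
  expect_equal(suppressWarnings(thresholdProfile(matrix(0, 10, 10)))@base, 0)
  expect_warning(thresholdProfile(matrix(3, 10, 10)), "constant")
})

test_that("IS/OS refinement recovers the true line on noiseless volumes", {
  g <- sceneGeometry(fieldDeg = c(12, 9), gridPx = c(96, 24))
  tr <- cleanTruth(seed = 10, geom = g, extension = 4, peakEcc = 1.5,
                   anterior = c(15, -40), center = c(48, 12))
  vol <- renderVolume(tr, g, depthPx = 96, jitterPx = 3)
  tp <- thresholdProfile(vol$volume$I[, , 12])
  # kernel sized for the coarse test grid: enough pixels inside the RPE band
  # that random states cannot average to a high DOPU by chance
  dp <- dopuVolume(vol, kernel = c(6, 8), tp = tp)
  ri <- refineIsos(vol, dp, vol$isosInitial)
  expect_true(all(ri$line == vol$isosTrue))
  expect_equal(sum(ri$flagged), 0)
  # jitter 0: the refinement is the identity
  vol0 <- renderVolume(tr, g, depthPx = 96, jitterPx = 0)
  ri0 <- refineIsos(vol0, dp, vol0$isosInitial)
  expect_true(all(ri0$line == vol0$isosInitial))
  # a window pushed fully inside the RPE flags exactly those A-scans
  deep <- vol$isosTrue + 7   # window [deep-1, deep+1] sits inside the RPE band
  ri2 <- refineIsos(vol, dp, deep, halfWidth = 1)
  expect_true(all(ri2$flagged))
  expect_true(all(ri2$line == deep))
})

test_that("en-face extraction averages the band and honours the threshold mask", {
  # hand-built volume: A-scan with 3 bright + 2 sub-threshold pixels in band
  d <- c(70, 4, 8)
  vol <- list(volume = list(I = array(0, d), Q = array(0, d),
                            U = array(0, d), V = array(0, d)),
              geometry = sceneGeometry(fieldDeg = c(4, 8), gridPx = c(4, 8)))
  line <- matrix(35L, 8, 4)
  vol$volume$I[33:37, , ] <- 1
  vol$volume$Q[33:37, , ] <- 0.5
  vol$volume$I[36:37, 2, 3] <- 1e-9     # sub-threshold in one A-scan
  tp <- new("ThresholdProfile", base = 0.1, decayPerPx = 0, depthPx = 70L)
  em <- extractEnface(vol, line, tp)
  expect_equal(em@I[3, 2], 1)           # mean over the 3 valid pixels only
  expect_equal(em@Q[1, 1], 0.5)         # constant band equals any single depth
  expect_true(all(validMask(em)))
  # A-scan independence: permuting B-scans permutes the output rows
  perm <- c(3, 1, 2, 5, 4, 7, 8, 6)
  vol2 <- vol
  for (nm in names(vol2$volume)) vol2$volume[[nm]] <- vol2$volume[[nm]][, , perm]
  em2 <- extractEnface(vol2, line, tp)
  expect_equal(em2@I, em@I[perm, ])
})

test_that("reference measurement takes the brightest pixel, shallowest on ties", {
  d <- c(50, 3, 4)
  vol <- list(volume = list(I = array(0.1, d), Q = array(0, d),
                            U = array(0, d), V = array(0, d)),
              geometry = sceneGeometry(fieldDeg = c(3, 4), gridPx = c(3, 4)))
  vol$refRange <- c(10, 20)
  vol$volume$I[15, , ] <- 2
  vol$volume$Q[15, , ] <- 1.5
  ref <- referenceMeasurement(vol)
  expect_true(all(ref@Q == 1.5))        # the single bright plane everywhere
  # two equal maxima: the shallower one wins
  vol$volume$I[12, 2, 2] <- 2
  vol$volume$Q[12, 2, 2] <- -1
  ref2 <- referenceMeasurement(vol)
  expect_equal(ref2@Q[2, 2], -1)
})

test_that("SNR estimation is the mean intensity-to-threshold ratio", {
  I <- matrix(2, 5, 5)
  expect_equal(estimateSnr(I, 2), 1)
  expect_equal(estimateSnr(2 * I, 2), 2 * estimateSnr(I, 2))
  expect_error(estimateSnr(I, 2, valid = matrix(FALSE, 5, 5)))
  # generator sweep: estimated SNR increases with the configured SNR
  g <- halfGeometry()
  est <- vapply(c(8, 14, 20, 26), function(db) {
    tr <- cleanTruth(seed = 11, geom = g, snrDb = db)
    sc <- renderEnface(tr, g)
    estimateSnr(sc$isos@I, sc$threshold, validMask(sc$isos))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("volume extraction reproduces the direct en-face rendering", {
  g <- sceneGeometry(fieldDeg = c(12, 9), gridPx = c(96, 24))
  tr <- cleanTruth(seed = 12, geom = g, extension = 4, peakEcc = 1.5,
                   anterior = c(15, -40), rotation = 10, center = c(48, 12))
  vol <- renderVolume(tr, g, depthPx = 96, jitterPx = 3)
  tp <- thresholdProfile(vol$volume$I[, , 12])
  dp <- dopuVolume(vol, kernel = c(6, 4), tp = tp)
  line <- refineIsos(vol, dp, vol$isosInitial)$line
  em <- extractEnface(vol, line, tp)
  ref <- referenceMeasurement(vol)
  pv <- polarizationFromStokes(compensateAnterior(em, ref))
  sc <- renderEnface(tr, g)
  pe <- polarizationFromStokes(compensateAnterior(sc$isos, sc$reference))
  v <- validMask(pv) & validMask(pe)
  expect_lt(max(abs(wrapAxis(axisMap(pv) - axisMap(pe)))[v]), 1e-8)
  expect_lt(max(abs(retardationMap(pv) - retardationMap(pe))[v]), 1e-8)
})
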