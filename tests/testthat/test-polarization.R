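test_that("retardation read-out follows the half-arccos rule", {
  for (case in list(c(1, 0), c(0, 45), c(-1, 90))) {
    s <- uniformStokes(c(case[1], sqrt(1 - case[1]^2), 0))
    expect_equal(retardationFromStokes(s)[1, 1], case[2], tolerance = 1e-10)
  }
})

test_that("retarder application round-trips retardation and axis", {
  s0 <- uniformStokes(c(1, 0, 0))  # circular input in the measurement frame
  for (delta in c(5, 30, 45, 60, 90)) {
    for (theta in c(-60, -30, 0, 30, 85)) {
      s1 <- applyRetarder(s0, retarder(delta, theta))
      expect_equal(retardationFromStokes(s1)[1, 1], delta, tolerance = 1e-9)
      if (delta < 90)  # at a half wave the transverse state (hence axis) vanishes
        expect_equal(axisFromStokes(s1)[1, 1], theta, tolerance = 1e-9)
    }
  }
})

test_that("axis maps are half-turn periodic and undefined without transverse component", {
  s0 <- uniformStokes(c(1, 0, 0))
  a <- axisFromStokes(applyRetarder(s0, retarder(30, -90)))
  b <- axisFromStokes(applyRetarder(s0, c(30, 90)))    # same physical axis
  expect_equal(a, b, tolerance = 1e-9)
  expect_true(all(is.na(axisFromStokes(s0))))          # no retardance, no axis
})

test_that("Poincare rotations preserve intensity and polarized magnitude, compose, invert", {
  set.seed(7)
  m <- function() matrix(rnorm(60), 6, 10)
  s <- new("StokesMap", I = matrix(2, 6, 10), Q = m(), U = m(), V = m(),
           valid = matrix(TRUE, 6, 10), surface = "t",
           geometry = sceneGeometry(gridPx = c(10, 6)))
  r1 <- retarder(37, 12); r2 <- retarder(64, -51)
  s1 <- applyRetarder(s, r1)
  expect_equal(s1@I, s@I)
  expect_equal(s1@Q^2 + s1@U^2 + s1@V^2, s@Q^2 + s@U^2 + s@V^2,
               tolerance = 1e-10)
  # identity and group inverse
  expect_equal(applyRetarder(s, retarder(0, 20)), s)
  back <- applyRetarder(applyRetarder(s, r1), c(-37, 12))
  expect_equal(back@Q, s@Q, tolerance = 1e-10)
  expect_equal(back@V, s@V, tolerance = 1e-10)
  # sequential application equals the composed rotation-matrix product
  rotmat <- function(delta, theta) {
    a <- 2 * delta * pi / 180; k <- c(0, cos(2 * theta * pi / 180),
                                      sin(2 * theta * pi / 180))
    K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  }
  s12 <- applyRetarder(applyRetarder(s, r1), r2)
  M <- rotmat(64, -51) %*% rotmat(37, 12)
  quv <- rbind(as.vector(s@Q), as.vector(s@U), as.vector(s@V))
  expect_equal(rbind(as.vector(s12@Q), as.vector(s12@U), as.vector(s12@V)),
               M %*% quv, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("axis extraction of random Stokes directions is uniform on [-90, 90)", {
  set.seed(5)
  n <- 1e5
  g <- matrix(rnorm(3 * n), 3)
  g <- g / rep(sqrt(colSums(g^2)), each = 3)
  s <- new("StokesMap", I = matrix(1, 1, n), Q = matrix(g[1, ], 1),
           U = matrix(g[2, ], 1), V = matrix(g[3, ], 1),
           valid = matrix(TRUE, 1, n), surface = "t",
           geometry = sceneGeometry(gridPx = c(n, 1)))
  ax <- axisFromStokes(s)
  h <- table(cut(as.vector(ax), breaks = seq(-90, 90, by = 10)))
  expect_gt(chisq.test(h)$p.value, 0.01)
})

test_that("Stokes averaging is idempotent, symmetric, and commutes with rotation", {
  s <- uniformStokes(c(0.6, 0.8, 0))
  expect_equal(averageStokes(s, kernel = c(5, 5)), s)
  # two pixels with opposite Q at equal intensity average to Q = 0
  s2 <- uniformStokes(c(1, 0, 0), ny = 1, nx = 2)
  s2@Q[1, 2] <- -1
  out <- averageStokes(s2, index = c(1L, 2L))
  expect_equal(unname(out["Q"]), 0)
  expect_equal(unname(out["I"]), 1)
  # empty selection: invalid output, not an exception
  s2@valid[] <- FALSE
  expect_true(all(is.na(averageStokes(s2, index = c(1L, 2L)))))
  # commutes with a global Poincare rotation
  set.seed(2)
  m <- function() matrix(rnorm(50), 5, 10)
  sr <- new("StokesMap", I = matrix(1, 5, 10), Q = m(), U = m(), V = m(),
            valid = matrix(TRUE, 5, 10), surface = "t",
            geometry = sceneGeometry(gridPx = c(10, 5)))
  r <- retarder(25, 40)
  a <- averageStokes(applyRetarder(sr, r), kernel = c(3, 3))
  b <- applyRetarder(averageStokes(sr, kernel = c(3, 3)), r)
  expect_equal(a@Q, b@Q, tolerance = 1e-12)
  expect_equal(a@V, b@V, tolerance = 1e-12)
})

test_that("Stokes-space averaging has less retardation bias than averaging retardation", {
  # constant 10 deg retardation field + noise: the mean of per-pixel
  # retardations acquires a positive offset; the retardation of the averaged
  # Stokes vector does not
  set.seed(31)
  delta <- 10
  truthState <- c(cos(2 * delta * pi / 180),
                  sin(2 * delta * pi / 180) * sin(2 * 30 * pi / 180),
                  -sin(2 * delta * pi / 180) * cos(2 * 30 * pi / 180))
  ny <- 60; nx <- 60
  sig <- 0.15
  s <- new("StokesMap", I = matrix(1, ny, nx),
           Q = matrix(truthState[1] + rnorm(ny * nx, 0, sig), ny),
           U = matrix(truthState[2] + rnorm(ny * nx, 0, sig), ny),
           V = matrix(truthState[3] + rnorm(ny * nx, 0, sig), ny),
           valid = matrix(TRUE, ny, nx), surface = "t",
           geometry = sceneGeometry(gridPx = c(nx, ny)))
  naive <- mean(retardationFromStokes(s))
  pooled <- averageStokes(s, index = matrix(TRUE, ny, nx))
  pooledDelta <- 0.5 * acos(pooled["Q"] /
                              sqrt(sum(pooled[c("Q", "U", "V")]^2))) * 180 / pi
  expect_lt(abs(pooledDelta - delta), abs(naive - delta))
  expect_gt(naive, delta)  # the artificial positive offset
})

test_that("DOPU is 1 for uniform states, 0 for antipodal mixtures, decreasing for noise", {
  s <- uniformStokes(c(0.6, 0, 0.8))
  expect_equal(max(abs(dopuMap(s, c(5, 5)) - 1)), 0, tolerance = 1e-12)
  # alternating antipodal states in equal proportion cancel
  s2 <- uniformStokes(c(1, 0, 0), ny = 2, nx = 10)
  flip <- outer(1:2, 1:10, function(r, c) (r + c) %% 2 == 0)
  s2@Q[flip] <- -1
  expect_equal(dopuMap(s2, c(2, 2))[1, 1], 0, tolerance = 1e-12)
  # isotropically random states: DOPU decreases with kernel size
  set.seed(8)
  n <- 80
  g <- matrix(rnorm(3 * n * n), 3)
  g <- g / rep(sqrt(colSums(g^2)), each = 3)
  s3 <- new("StokesMap", I = matrix(1, n, n), Q = matrix(g[1, ], n),
            U = matrix(g[2, ], n), V = matrix(g[3, ], n),
            valid = matrix(TRUE, n, n), surface = "t",
            geometry = sceneGeometry(gridPx = c(n, n)))
  d5 <- mean(dopuMap(s3, c(5, 5)))
  d15 <- mean(dopuMap(s3, c(15, 15)))
  expect_lt(d15, d5)
  expect_true(all(dopuMap(s3, c(10, 10)) <= 1))
})

test_that("retardation converts to nanometres as delta/360 * lambda", {
  expect_equal(retardationDegToNm(9, 860), 21.5)
  expect_equal(retardationDegToNm(0, 1300), 0)
  expect_equal(retardationDegToNm(360, 860), 860)
  expect_error(retardationDegToNm(-1))
})

test_that("anterior compensation recovers the sample exactly from an exact reference", {
  geom <- sceneGeometry(gridPx = c(40, 30))
  tr <- cleanTruth(seed = 2, geom = geom, extension = 6, anterior = c(20, 35),
                   center = c(20, 15))
  sc <- renderEnface(tr, geom)
  # zero anterior: compensation is the identity
  tr0 <- cleanTruth(seed = 2, geom = geom, extension = 6, center = c(20, 15))
  sc0 <- renderEnface(tr0, geom)
  comp0 <- compensateAnterior(sc0$isos, sc0$reference)
  expect_equal(comp0@Q, sc0$isos@Q, tolerance = 1e-9)
  # with anterior (20 deg @ 35 deg): axis recovered within 0.5 deg RMS
  pol <- polarizationFromStokes(compensateAnterior(sc$isos, sc$reference))
  v <- validMask(pol)
  rms <- sqrt(mean(wrapAxis(axisMap(pol) - sc$truthAxis)[v]^2))
  expect_lt(rms, 0.5)
})
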