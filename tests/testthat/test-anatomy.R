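sphereTracks <- function(n = 200, R = 300, noise = 0, nFrames = 1,
                         thetaMax = pi / 2, center = c(0, 0, 0), seed = 2) {
  set.seed(seed)
  z <- runif(n, cos(thetaMax), 1)
  ph <- runif(n, 0, 2 * pi)
  st <- sqrt(1 - z^2)
  U <- cbind(st * cos(ph), st * sin(ph), z)
  rows <- do.call(rbind, lapply(0:(nFrames - 1L), function(f) {
    P <- U * (R + rnorm(n, sd = noise)) +
      matrix(center, n, 3, byrow = TRUE)
    data.frame(track_id = seq_len(n), frame = f, x_um = P[, 1],
               y_um = P[, 2], z_um = P[, 3], is_evl = TRUE)
  }))
  CellTracks(rows)
}

test_that("an exact sphere is recovered with radial normals", {
  tr <- sphereTracks(R = 300, center = c(10, -5, 20))
  surf <- fitEVLSurface(tr)
  expect_equal(surf@radius[1], 300, tolerance = 1e-3)
  expect_equal(surf@center[1, ], c(10, -5, 20), tolerance = 0.1)
  expect_lt(surf@residualRMS[1], 0.05)
  pts <- rbind(c(10, -5, 320), c(310, -5, 20))
  nrm <- surfaceNormal(surf, 0, pts)
  expect_equal(nrm[1, ], c(0, 0, 1), tolerance = 1e-3)
  expect_equal(nrm[2, ], c(1, 0, 0), tolerance = 1e-3)
  # the animal pole cap gives a +z axis
  expect_equal(animalAxis(surf, 0)[3], max(abs(animalAxis(surf, 0))))
})

test_that("noisy hemisphere fit has bounded residuals and zero-median depth", {
  tr <- sphereTracks(R = 300, noise = 1)
  surf <- fitEVLSurface(tr)
  expect_lte(surf@residualRMS[1], 2)
  d <- tracksData(tr)
  dep <- depthOf(as.matrix(d[, c("x_um", "y_um", "z_um")]), surf, 0,
                 d = 16.1095)
  expect_equal(median(dep), 0, tolerance = 0.02)
})

test_that("surface fitting is rotation equivariant", {
  tr <- sphereTracks(R = 250, noise = 0.5)
  R3 <- rotationMatrix3(c(1, -1, 2), 55)
  tr2 <- transformTracks(tr, R3)
  s1 <- fitEVLSurface(tr)
  s2 <- fitEVLSurface(tr2)
  expect_equal(s2@axis[1, ], as.vector(R3 %*% s1@axis[1, ]),
               tolerance = 1e-3)
  expect_equal(s2@radius, s1@radius, tolerance = 1e-3)
  p <- c(0, 0, 250)
  n1 <- surfaceNormal(s1, 0, matrix(p, 1))[1, ]
  n2 <- surfaceNormal(s2, 0, matrix(as.vector(R3 %*% p), 1))[1, ]
  expect_equal(n2, as.vector(R3 %*% n1), tolerance = 5e-3)
  expect_error(fitEVLSurface(CellTracks(data.frame(
    track_id = 1:5, frame = 0L, x_um = 1:5, y_um = 1, z_um = 1,
    is_evl = TRUE))), "EVL")
})

test_that("depths are measured inward in units of cell diameters", {
  tr <- sphereTracks(R = 300)
  surf <- fitEVLSurface(tr)
  expect_equal(depthOf(matrix(c(0, 0, 300), 1), surf, 0, d = 10), 0,
               tolerance = 5e-3)
  expect_equal(depthOf(matrix(c(0, 0, 280), 1), surf, 0, d = 10), 2,
               tolerance = 5e-3)
  expect_equal(depthOf(matrix(c(0, 0, 300 - 16.1095), 1), surf, 0,
                       d = 16.1095), 1, tolerance = 5e-3)
})

test_that("direction classification uses the lateral band around the normal", {
  nrm <- c(0, 0, 1)
  expect_equal(classifyDirection(c(0, 0, 10), nrm), "up")
  expect_equal(classifyDirection(c(0, 0, -10), nrm), "down")
  expect_equal(classifyDirection(c(20, 0, 0), nrm), "lateral")
  expect_equal(classifyDirection(c(0, 0, 7), nrm), "lateral")   # inclusive
  expect_equal(classifyDirection(c(0, 0, 7.01), nrm), "up")
  expect_error(classifyDirection(c(0, 0, 0), nrm), "zero-length")
})

test_that("direction classes partition events and mirror antisymmetrically", {
  set.seed(8)
  disp <- matrix(rnorm(300 * 3, sd = 8), ncol = 3)
  nrm <- c(0, 0, 1)
  cls <- apply(disp, 1, classifyDirection, normal = nrm)
  expect_equal(sum(cls == "up") + sum(cls == "down") +
               sum(cls == "lateral"), 300L)
  clsM <- apply(-disp, 1, classifyDirection, normal = nrm)
  expect_equal(sum(clsM == "up"), sum(cls == "down"))
  expect_equal(sum(clsM == "down"), sum(cls == "up"))
  expect_equal(sum(clsM == "lateral"), sum(cls == "lateral"))
})

test_that("sector assignment is a cone about the animal-vegetal axis", {
  tr <- sphereTracks(R = 300)
  surf <- fitEVLSurface(tr)
  pole <- matrix(c(0, 0, 290), 1)
  equ <- matrix(c(290, 0, 0), 1)
  expect_equal(assignSector(pole, surf, 0, halfAngle = 45), "S1")
  expect_equal(assignSector(equ, surf, 0, halfAngle = 80), "S2")
  # a point exactly on the (fitted) axis is S1 even for a tiny cone
  onAxis <- matrix(surf@center[1, ] + 290 * animalAxis(surf, 0), 1)
  expect_equal(assignSector(onAxis, surf, 0, halfAngle = 0.5), "S1")
  expect_equal(assignSector(matrix(c(40, 0, 285), 1), surf, 0,
                            halfAngle = 0), "S2")
})

test_that("time windows are half-open with a closed last edge", {
  # frame at minute 50 -> second window; 0 -> first; 126 -> last (closed)
  expect_equal(assignTimeWindow(50 / 1.05), "T2")
  expect_equal(assignTimeWindow(0), "T1")
  expect_equal(assignTimeWindow(120), "T3")  # 126 min
  expect_equal(assignTimeWindow(39), "T1")   # 40.95 min
  expect_equal(assignTimeWindow(40), "T2")   # exactly 42 min: half-open
  expect_true(is.na(assignTimeWindow(200)))
  expect_equal(assignTimeWindow(c(0, 60, 100)), c("T1", "T2", "T3"))
})

test_that("annotation classifies planted radial events correctly", {
  fx <- smallFixture()
  ev <- detectEvents(fx$tracks, fx$graphs)
  ev <- verifyEvents(computeKinematics(fx$tracks, ev))
  surf <- fitEVLSurface(fx$tracks)
  ev <- annotateEvents(ev, fx$tracks, surf)
  m <- matchGroundTruth(ev, fx$truth)
  ok <- !is.na(m$matchedEvent)
  expect_equal(ev$direction[ok],
               fx$truth$direction[m$matchedEvent[ok]])
  expect_true(all(ev$depth_diam[ok] > 0))
  expect_true(all(ev$time_window[ok] %in% c("T1", "T2", "T3")))
})
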