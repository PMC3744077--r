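makeTracks <- function(posList, frameInterval = 1.05) {
  # posList: named list track_id -> matrix (nFrames x 3)
  rows <- lapply(names(posList), function(id) {
    P <- posList[[id]]
    data.frame(track_id = as.integer(id), frame = seq_len(nrow(P)) - 1L,
               x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
  })
  CellTracks(do.call(rbind, rows), frameInterval = frameInterval)
}

test_that("a shared translation is compensated exactly", {
  nF <- 10
  drift <- cbind(cumsum(rep(2, nF)), cumsum(rep(-1, nF)), 0)
  base <- list(`1` = c(0, 0, 0), `2` = c(10, 0, 0), `3` = c(0, 10, 0),
               `4` = c(7, 7, 5))
  pos <- lapply(base, function(p) sweep(drift, 2, p, "+"))
  tr <- makeTracks(pos)
  path <- registerLocal(tr, 1L, c(0, nF - 1))
  expect_equal(max(abs(as.matrix(path[, c("x", "y", "z")]))), 0,
               tolerance = 1e-9)
})

test_that("motion relative to static neighbors equals absolute motion", {
  nF <- 8
  mover <- cbind(2 * (0:(nF - 1)), 0, 0)
  pos <- list(`1` = mover,
              `2` = matrix(c(0, 10, 0), nF, 3, byrow = TRUE),
              `3` = matrix(c(10, 10, 0), nF, 3, byrow = TRUE))
  tr <- makeTracks(pos)
  path <- registerLocal(tr, 1L, c(0, nF - 1))
  expect_equal(path$x, 2 * (0:(nF - 1)))
  expect_equal(path$y, rep(0, nF))
})

test_that("principal direction and directedness behave on canonical paths", {
  straight <- data.frame(frame = 0:9, x = seq(0, 18, by = 2), y = 0, z = 0)
  md <- mainDirection(straight)
  expect_equal(abs(md$direction), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(md$direction[1], 1)  # points from early to late extremum
  expect_equal(md$eigenvalues[2:3], c(0, 0), tolerance = 1e-9)
  expect_equal(directedness(straight), 1, tolerance = 1e-12)

  # planar circle: covariance eigenvalues (r^2/2, r^2/2, 0) -> r_dir 1/2
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- data.frame(frame = seq_along(th) - 1L,
                       x = cos(th), y = sin(th), z = 0)
  expect_equal(directedness(circle), 0.5, tolerance = 1e-3)

  # isotropic 3D cloud -> 1/3
  set.seed(4)
  cloud <- data.frame(frame = 0:9999, x = rnorm(1e4), y = rnorm(1e4),
                      z = rnorm(1e4))
  expect_equal(directedness(cloud), 1 / 3, tolerance = 0.05)
  expect_equal(sort(mainDirection(cloud)$eigenvalues),
               rep(1, 3), tolerance = 0.06)

  # rotation equivariance
  R <- rotationMatrix3(c(1, 1, 0), 40)
  P <- as.matrix(straight[, c("x", "y", "z")]) %*% t(R)
  mdR <- mainDirection(data.frame(frame = 0:9, x = P[, 1], y = P[, 2],
                                  z = P[, 3]))
  expect_equal(mdR$direction, as.vector(R %*% md$direction),
               tolerance = 1e-9)
  expect_error(mainDirection(data.frame(frame = 0:1, x = 1, y = 1, z = 1)),
               "distinct")
})

test_that("refinement clips the window at the projection extrema", {
  # path overshoots to 15 then returns to 12
  xs <- c(0, 3, 6, 9, 12, 15, 12)
  path <- data.frame(frame = 0:6, x = xs, y = 0, z = 0)
  md <- mainDirection(path)
  ref <- refineEvent(path, md$direction)
  expect_equal(ref$window, c(0, 5))
  expect_equal(abs(ref$displacement[1]), 15)
  # monotone path: full window
  mono <- data.frame(frame = 0:5, x = 0:5, y = 0, z = 0)
  expect_equal(refineEvent(mono, c(1, 0, 0))$window, c(0, 5))
  # time reversal flips the displacement sign
  revPath <- path[rev(seq_len(nrow(path))), ]
  revPath$frame <- 0:6
  refR <- refineEvent(revPath, mainDirection(revPath)$direction)
  expect_equal(abs(refR$displacement[1]), 15)
  expect_error(refineEvent(data.frame(frame = 0:1, x = c(0, 0), y = 0,
                                      z = c(0, 0)), c(1, 0, 0)),
               "zero-extent|distinct")
})

test_that("speeds follow the revised path arithmetic", {
  straight <- data.frame(frame = 0:12, x = seq(0, 12, length.out = 13),
                         y = 0, z = 0)
  sp <- eventSpeeds(straight, frameInterval = 1.05)
  expect_equal(sp$duration, 12.6)
  expect_equal(sp$effective_speed, 12 / 12.6, tolerance = 1e-9)
  expect_equal(sp$instantaneous_speed, 12 / 12.6, tolerance = 1e-9)

  # zig-zag: net 6 um, total 18 um, 6 steps of 1.05 min
  zig <- data.frame(frame = 0:6, x = c(0, 4, 2, 6, 4, 8, 6), y = 0, z = 0)
  spz <- eventSpeeds(zig, frameInterval = 1.05)
  expect_equal(spz$abs_displacement, 6)
  expect_equal(spz$path_length, 18)
  expect_equal(spz$effective_speed, 6 / 6.3, tolerance = 1e-9)
  expect_equal(spz$instantaneous_speed, 18 / 6.3, tolerance = 1e-9)
  expect_gte(spz$instantaneous_speed, spz$effective_speed)
})

test_that("verification is an inclusive conjunctive threshold filter", {
  ev <- data.frame(abs_disp_um = c(5.9, 12, 12, 6.0, 20),
                   r_dir = c(0.95, 0.84, 0.95, 0.85, 0.20))
  out <- verifyEvents(ev)
  expect_equal(out$verified, c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("event kinematics are invariant to a global translation", {
  fx <- smallFixture()
  ev <- detectEvents(fx$tracks, fx$graphs)
  k0 <- computeKinematics(fx$tracks, ev)
  tr2 <- translateTracks(fx$tracks, c(500, -200, 50))
  k1 <- computeKinematics(tr2, ev)
  expect_equal(k1$abs_disp_um, k0$abs_disp_um, tolerance = 1e-9)
  expect_equal(k1$r_dir, k0$r_dir, tolerance = 1e-9)
  expect_equal(k1$dx, k0$dx, tolerance = 1e-9)
  expect_true(all(k0$path_len_um >= k0$abs_disp_um - 1e-9))
})

test_that("planted displacements are recovered by the motion stage", {
  fx <- smallFixture()
  ev <- detectEvents(fx$tracks, fx$graphs)
  ev <- verifyEvents(computeKinematics(fx$tracks, ev))
  m <- matchGroundTruth(ev, fx$truth)
  matched <- ev[!is.na(m$matchedEvent), ]
  # planted center-cell displacement is one plantDisplacement = 16 um
  expect_equal(median(matched$abs_disp_um), 16, tolerance = 0.1)
  expect_true(all(matched$verified))
  expect_true(all(matched$r_dir > 0.9))
})
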