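test_that("generation is deterministic given the seed", {
  cfg <- syntheticConfig(nCells = 80L, nFrames = 25L,
                         nPlantedEvents = c(up = 1, down = 1),
                         rngSeed = 5L)
  e1 <- generateEmbryo(cfg)
  e2 <- generateEmbryo(cfg)
  expect_identical(tracksData(e1$tracks), tracksData(e2$tracks))
  expect_identical(e1$truth, e2$truth)
  e3 <- generateEmbryo(syntheticConfig(nCells = 80L, nFrames = 25L,
                                       nPlantedEvents = c(up = 1, down = 1),
                                       rngSeed = 6L))
  expect_false(identical(tracksData(e1$tracks), tracksData(e3$tracks)))
})

test_that("a noise-free embryo without events is stationary", {
  cfg <- syntheticConfig(nCells = 60L, nFrames = 10L, noiseSigma = 0,
                         mitosisGapRate = 0, rngSeed = 2L)
  emb <- generateEmbryo(cfg)
  expect_equal(nrow(emb$truth), 0L)
  d <- tracksData(emb$tracks)
  moved <- vapply(split(seq_len(nrow(d)), d$track_id), function(rows)
    max(apply(d[rows, c("x_um", "y_um", "z_um")], 2, function(x)
      diff(range(x)))), numeric(1))
  expect_equal(max(moved), 0)
})

test_that("planted counts and directions are honoured by construction", {
  cfg <- syntheticConfig(nCells = 300L, nFrames = 60L,
                         nPlantedEvents = c(up = 4, down = 4, lateral = 2),
                         rngSeed = 9L)
  emb <- generateEmbryo(cfg)
  expect_equal(nrow(emb$truth), 10L)
  expect_equal(sum(emb$truth$direction == "up"), 4L)
  expect_equal(sum(emb$truth$direction == "down"), 4L)
  expect_equal(sum(emb$truth$direction == "lateral"), 2L)
  expect_equal(sum(emb$truth$direction == "up") /
               sum(emb$truth$direction == "down"), 1)
  # every referenced track exists and windows lie inside the recording
  d <- tracksData(emb$tracks)
  ids <- unique(d$track_id)
  expect_true(all(c(emb$truth$center_track, emb$truth$neighbor_a,
                    emb$truth$neighbor_b) %in% ids))
  expect_true(all(emb$truth$frame_start >= 0))
  expect_true(all(emb$truth$frame_end < cfg$nFrames))
  # planted displacement magnitude is one plantDisplacement
  disp <- sqrt(emb$truth$dx_um^2 + emb$truth$dy_um^2 + emb$truth$dz_um^2)
  expect_equal(disp, rep(cfg$plantDisplacement, 10), tolerance = 1e-9)
})

test_that("EVL nuclei lie radially outside all deep cells", {
  fx <- smallFixture()
  d <- tracksData(fx$tracks)
  r <- sqrt(d$x_um^2 + d$y_um^2 + d$z_um^2)
  for (f in unique(d$frame)) {
    sel <- d$frame == f
    expect_gt(min(r[sel & d$is_evl]), max(r[sel & !d$is_evl]))
  }
})

test_that("over-full planting requests fail explicitly", {
  cfg <- syntheticConfig(nCells = 60L, nFrames = 20L, embryoRadius = 115,
                         nPlantedEvents = c(up = 400), rngSeed = 1L)
  expect_error(generateEmbryo(cfg), "cannot place")
})

test_that("planted center paths move monotonically through the midplane", {
  pos <- rbind(i = c(-8, 0, 0), j = c(8, 0, 0), k = c(0, -16, 0))
  path <- plantIntercalation(pos, duration = 10)
  expect_equal(path[10, ], c(0, 0, 0))           # ends at the midpoint
  expect_true(all(diff(path[, 2]) > 0))          # monotone along the normal
  # the enclosing angle at k is linear in time
  wk <- vapply(seq_len(10), function(t)
    pairwiseAngles(pos[1, ], pos[2, ], path[t, ])[["w_k"]], numeric(1))
  expect_equal(wk, seq(wk[1], 180, length.out = 10), tolerance = 1e-6)
  expect_error(plantIntercalation(rbind(c(-8, 0, 0), c(8, 0, 0),
                                        c(0, 0, 0)), 10),
               "collinear")
})

test_that("fixtures round-trip through CSV", {
  cfg <- syntheticConfig(nCells = 60L, nFrames = 16L, eventDuration = 6L,
                         nPlantedEvents = c(up = 1), rngSeed = 4L)
  emb <- generateEmbryo(cfg)
  dir <- tempfile("fixture")
  paths <- writeFixture(emb$tracks, emb$truth, dir)
  back <- readTracks(paths[["tracks"]])
  expect_equal(tracksData(back), tracksData(emb$tracks))
  truthBack <- readGroundTruth(paths[["truth"]])
  expect_equal(truthBack, emb$truth)
  # row count equals the sum of per-track frame counts
  nRows <- length(readLines(paths[["tracks"]])) - 1L
  expect_equal(nRows, nrow(tracksData(emb$tracks)))
  # empty truth: header-only file
  paths2 <- writeFixture(emb$tracks, emb$truth[0, ], tempfile("fx2"))
  expect_equal(length(readLines(paths2[["truth"]])), 1L)
  unlink(c(dir, dirname(paths2[1])), recursive = TRUE)
})

test_that("mitosis gaps split tracks with short, bounded interruptions", {
  cfg <- syntheticConfig(nCells = 200L, nFrames = 40L,
                         mitosisGapRate = 0.01, rngSeed = 8L)
  emb <- generateEmbryo(cfg)
  d <- tracksData(emb$tracks)
  perTrack <- split(d$frame, d$track_id)
  # all tracks are contiguous (gap model: termination + new id)
  expect_true(all(vapply(perTrack, function(f)
    all(diff(sort(f)) == 1L), logical(1))))
  # splitting happened: more tracks than the requested cell count
  expect_gt(length(perTrack), 190L)
})
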