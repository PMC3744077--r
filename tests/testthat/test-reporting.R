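fakeEvents <- function(nUp, nDown, nLat) {
  n <- nUp + nDown + nLat
  data.frame(event_id = seq_len(n),
             center = seq_len(n),
             frame_start = rep(0L, n), frame_end = rep(10L, n),
             frame_start_rev = rep(0L, n), frame_end_rev = rep(10L, n),
             direction = rep(c("up", "down", "lateral"),
                             c(nUp, nDown, nLat)),
             verified = rep(TRUE, n))
}

test_that("count summaries reproduce the ratio and CI arithmetic", {
  cs <- countSummary(fakeEvents(50, 50, 68))
  expect_equal(unname(cs$counts), c(50L, 50L, 68L))
  expect_equal(unname(cs$ratios["up_down"]), 1)
  expect_equal(unname(cs$ratios["lateral_radial"]), 0.68)
  cs100 <- countSummary(fakeEvents(100, 0, 0))
  expect_equal(unname(cs100$ci["up", ]), c(100 - 19.6, 100 + 19.6),
               tolerance = 1e-9)
  expect_true(is.na(cs100$ratios["up_down"]))   # zero denominator
  empty <- countSummary(fakeEvents(0, 0, 0))
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
  expect_true(all(is.na(empty$ratios)))
  expect_equal(unname(empty$ci[, "lower"]), c(0, 0, 0))
  # CI bounds always bracket the count
  cs2 <- countSummary(fakeEvents(7, 3, 5))
  expect_true(all(cs2$ci[, "lower"] <= cs2$counts))
  expect_true(all(cs2$ci[, "upper"] >= cs2$counts))
  # exact Garwood intervals cover small counts
  g <- countSummary(fakeEvents(2, 0, 0), exactCI = TRUE)
  expect_lt(g$ci["up", "lower"], 2)
  expect_gt(g$ci["up", "upper"], 5)
})

test_that("history trees count successive events with parent fractions", {
  ev <- data.frame(event_id = 1:6,
                   center = c(1, 1, 1, 2, 2, 3),
                   frame_start_rev = c(0, 10, 20, 0, 10, 0),
                   direction = c("up", "down", "lateral",
                                 "up", "up", "down"),
                   verified = TRUE)
  ht <- historyTree(ev)
  expect_equal(ht$count[ht$depth == 1 & ht$path == "up"], 2L)
  expect_equal(ht$count[ht$depth == 1 & ht$path == "down"], 1L)
  expect_equal(sum(ht$count[ht$depth == 1]), 3L)  # cells with >= 1 event
  expect_equal(ht$count[ht$path == "up/down/lateral"], 1L)
  # fractions of the children of any node sum to 1
  expect_equal(sum(ht$fraction[ht$depth == 1]), 1)
  for (p in ht$path[ht$depth < 3]) {
    kids <- ht[ht$depth == lengths(strsplit(p, "/")) + 1L &
               startsWith(ht$path, paste0(p, "/")), ]
    if (nrow(kids))
      expect_equal(sum(kids$fraction), 1)
  }
})

test_that("depth profiles normalise by cell-frame occupancy", {
  fx <- smallFixture()
  surf <- fitEVLSurface(fx$tracks)
  ev <- fakeEvents(2, 1, 0)
  ev$depth_diam <- c(1.2, 1.3, 2.7)
  dp <- depthProfile(ev, fx$tracks, surf, d = 16)
  expect_true(all(dp$rate[dp$n_observations > 0] >= 0, na.rm = TRUE))
  up12 <- dp[dp$direction == "up" & dp$depth_lo == 1.0, ]
  expect_equal(up12$n_events, 2L)
  down25 <- dp[dp$direction == "down" & dp$depth_lo == 2.5, ]
  expect_equal(down25$n_events, 1L)
  # occupancy appears in the denominator: doubling observations (two
  # frames instead of one) halves the rate for the same events
  oneFrame <- CellTracks(tracksData(fx$tracks)[
    tracksData(fx$tracks)$frame == 0L, ])
  twoFrames <- CellTracks(tracksData(fx$tracks)[
    tracksData(fx$tracks)$frame <= 1L, ])
  s1 <- fitEVLSurface(oneFrame)
  s2 <- fitEVLSurface(twoFrames)
  d1 <- depthProfile(ev, oneFrame, s1, d = 16)
  d2 <- depthProfile(ev, twoFrames, s2, d = 16)
  r1 <- d1$rate[d1$direction == "up" & d1$depth_lo == 1.0]
  r2 <- d2$rate[d2$direction == "up" & d2$depth_lo == 1.0]
  expect_equal(r1 / r2, 2, tolerance = 0.2)
})

test_that("sector exit ratios follow the window arithmetic", {
  fx <- smallFixture()
  surf <- fitEVLSurface(fx$tracks)
  ev <- verifyEvents(computeKinematics(fx$tracks,
                                       detectEvents(fx$tracks, fx$graphs)))
  ev <- annotateEvents(ev, fx$tracks, surf)
  se <- sectorExitRatio(fx$tracks, ev, surf, halfAngle = 45,
                        windowMinutes = 15)
  expect_true(all(se$n_exits >= 0))
  expect_true(all(se$n_radial >= 0))
  ok <- !is.na(se$ratio)
  expect_equal(se$ratio[ok], se$n_exits[ok] / se$n_radial[ok])
  expect_true(all(is.na(se$ratio[se$n_radial == 0])))
})

test_that("the full pipeline is consistent, conservative and deterministic", {
  fx <- smallFixture()
  rep1 <- runPipeline(fx$tracks)
  ev <- rep1@events
  ver <- ev[ev$verified, ]
  # count conservation across every stratification
  expect_equal(sum(rep1@summary$counts), nrow(ver))
  expect_equal(sum(table(ver$time_window)), nrow(ver))
  expect_equal(sum(table(ver$sector)), nrow(ver))
  # planted recovery end to end
  m <- matchGroundTruth(ver, fx$truth)
  expect_gte(m$sensitivity, 5 / 6)
  # determinism
  rep2 <- runPipeline(fx$tracks)
  expect_equal(rep1@events, rep2@events)
  expect_equal(rep1@summary$counts, rep2@summary$counts)
  expect_equal(rep1@coefficients, rep2@coefficients)
  # report files are written
  dir <- tempfile("report")
  paths <- writeReport(rep1, dir)
  expect_true(all(file.exists(paths)))
  unlink(dir, recursive = TRUE)
})

test_that("mirroring all displacements swaps up and down counts", {
  fx <- smallFixture()
  surf <- fitEVLSurface(fx$tracks)
  ev <- verifyEvents(computeKinematics(fx$tracks,
                                       detectEvents(fx$tracks, fx$graphs)))
  ev <- annotateEvents(ev, fx$tracks, surf)
  cs0 <- countSummary(ev)
  evM <- ev
  evM$dx <- -evM$dx; evM$dy <- -evM$dy; evM$dz <- -evM$dz
  evM <- annotateEvents(evM, fx$tracks, surf)
  csM <- countSummary(evM)
  expect_equal(csM$counts[["up"]], cs0$counts[["down"]])
  expect_equal(csM$counts[["down"]], cs0$counts[["up"]])
  expect_equal(csM$counts[["lateral"]], cs0$counts[["lateral"]])
  if (cs0$counts[["down"]] > 0 && csM$counts[["down"]] > 0)
    expect_equal(csM$ratios[["up_down"]], 1 / cs0$ratios[["up_down"]])
})
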