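tplDefault <- intercalationTemplate(aStart = 150)

test_that("template values interpolate linearly with an a_ij cutoff at T2", {
  v0 <- templateValues(tplDefault, 0)
  expect_equal(v0[1, ], tplDefault@startValues)
  v1 <- templateValues(tplDefault, 1)
  expect_equal(v1[1, ], tplDefault@endValues)
  expect_equal(v1[1, "w_k"], c(w_k = 180))
  # a_ij is exactly zero from T2 on
  u <- seq(0.5, 1, by = 0.01)
  expect_true(all(templateValues(tplDefault, u)[, "a_ij"] == 0))
  expect_error(templateValues(tplDefault, 1.2), "\\[0, 1\\]")
  expect_error(templateValues(tplDefault, -0.1), "\\[0, 1\\]")
})

test_that("template construction enforces the triangular-to-linear contract", {
  expect_error(intercalationTemplate(aStart = 150, endAngles = c(0, 0, 90)),
               "w_k")
  expect_error(intercalationTemplate(aStart = 150,
                                     startAngles = c(80, 80, 80)),
               "sum to 180")
  expect_error(new("IntercalationTemplate",
                   startValues = tplDefault@startValues,
                   endValues = replace(tplDefault@endValues, 4, 5),
                   t2Fraction = 0.5),
               "a_ij")
})

test_that("fit error vanishes exactly on an ideal template series", {
  u <- seq(0, 1, length.out = 15)
  series <- as.data.frame(templateValues(tplDefault, u))
  series$frame <- seq_len(15) - 1L
  expect_equal(fitError(series, tplDefault), 0, tolerance = 1e-12)
  # linearity in the weights
  noisy <- series
  noisy$w_i <- noisy$w_i + 5
  d1 <- fitError(noisy, tplDefault)
  d2 <- fitError(noisy, tplDefault, wMse = 2 * detectionParams()$wMse,
                 wPar = 2 * detectionParams()$wPar)
  expect_gt(d1, 0)
  expect_equal(d2, 2 * d1)
  # a non-intercalating (constant) series scores strictly worse
  flat <- series
  for (cn in c("w_i", "w_j", "w_k")) flat[[cn]] <- 60
  flat$a_ij <- 150; flat$a_jk <- 150; flat$a_ki <- 150
  expect_gt(fitError(flat, tplDefault), fitError(series, tplDefault))
  expect_error(fitError(series, tplDefault, wMse = rep(-1, 6)),
               "non-negative")
})

test_that("scores are exp(-d) and strictly decreasing in d", {
  expect_equal(eventScore(0), 1)
  expect_equal(eventScore(log(2)), 0.5)
  d <- seq(0, 3, by = 0.1)
  expect_true(all(diff(eventScore(d)) < 0))
  expect_error(eventScore(-0.1), ">= 0")
})

test_that("feature series reproduce geometry and adjacency", {
  fx <- smallFixture()
  tr <- fx$truth[1, ]
  fs <- featureSeries(fx$tracks, fx$graphs, tr$neighbor_a, tr$neighbor_b,
                      tr$center_track, c(tr$frame_start, tr$frame_end))
  expect_equal(nrow(fs), tr$frame_end - tr$frame_start + 1L)
  expect_equal(rowSums(fs[, c("w_i", "w_j", "w_k")]),
               rep(180, nrow(fs)), tolerance = 1e-9)
  expect_true(all(fs[, c("a_ij", "a_jk", "a_ki")] >= 0))
  # the planted neighbor pair loses contact by the end of the window
  expect_gt(fs$a_ij[1], 0)
  expect_equal(fs$a_ij[nrow(fs)], 0)
  # w_k rises toward the linear configuration
  expect_gt(fs$w_k[nrow(fs)], 160)
})

test_that("planted events are recovered on the small fixture", {
  fx <- smallFixture()
  ev <- detectEvents(fx$tracks, fx$graphs)
  m <- matchGroundTruth(ev, fx$truth)
  expect_gte(m$sensitivity, 5 / 6)
  expect_lte(m$fdr, 1 / 6)
  expect_true(all(ev$score >= 0.85))
  expect_true(all(ev$score == eventScore(ev$d_err)))
})

test_that("a quiescent embryo yields no events", {
  cfg <- syntheticConfig(nCells = 120L, nFrames = 20L, noiseSigma = 0,
                         nPlantedEvents = c(up = 0), mitosisGapRate = 0,
                         rngSeed = 3L)
  emb <- generateEmbryo(cfg)
  ev <- detectEvents(emb$tracks)
  expect_equal(nrow(ev), 0L)
  # degenerate input: a single frame cannot host any window
  one <- tracksData(emb$tracks)
  one <- one[one$frame == 0L, ]
  expect_equal(nrow(detectEvents(CellTracks(one))), 0L)
})

test_that("relabeling track ids permutes but does not change events", {
  fx <- smallFixture()
  ev0 <- detectEvents(fx$tracks, fx$graphs)
  d <- tracksData(fx$tracks)
  ids <- sort(unique(d$track_id))
  set.seed(9)
  newIds <- sample(ids + 1000L)
  map <- stats::setNames(newIds, ids)
  d$track_id <- unname(map[as.character(d$track_id)])
  ev1 <- detectEvents(CellTracks(d, frameInterval = frameInterval(fx$tracks)))
  expect_equal(nrow(ev1), nrow(ev0))
  key1 <- sprintf("%d:%d:%d-%d", ev1$center,
                  pmin(ev1$neighbor_a, ev1$neighbor_b),
                  ev1$frame_start, ev1$frame_end)
  key0b <- sprintf("%d:%d:%d-%d", map[as.character(ev0$center)],
                   pmin(map[as.character(ev0$neighbor_a)],
                        map[as.character(ev0$neighbor_b)]),
                   ev0$frame_start, ev0$frame_end)
  expect_setequal(key1, key0b)
  expect_equal(sort(exp(-ev1$d_err)), sort(exp(-ev0$d_err)),
               tolerance = 1e-9)
})

test_that("overlapping windows of one triple are joined to one event", {
  fx <- smallFixture()
  ev <- detectEvents(fx$tracks, fx$graphs,
                     params = detectionParams(scoreThreshold = 0.5))
  key <- paste(ev$center, pmin(ev$neighbor_a, ev$neighbor_b),
               pmax(ev$neighbor_a, ev$neighbor_b))
  for (k in unique(key[duplicated(key)])) {
    w <- ev[key == k, ]
    w <- w[order(w$frame_start), ]
    expect_true(all(w$frame_start[-1] > w$frame_end[-nrow(w)]))
  }
})
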