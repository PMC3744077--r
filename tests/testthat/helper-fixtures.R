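# Shared synthetic fixtures, built once per test run.
#
# smallFixture: 250 cells, 60 frames, 3 up + 3 down planted events -- fast
#   enough for per-module tests that need real tessellations.
# referenceFixture: the standard 400-cell, 120-frame fixture with 20 up +
#   20 down planted events (documented seed 1) used for end-to-end
#   recovery checks; detection is run once at a low threshold so counts at
#   any higher threshold can be read off the kept candidates.

.fixtureCache <- new.env(parent = emptyenv())

smallFixture <- function() {
  if (is.null(.fixtureCache$small)) {
    cfg <- syntheticConfig(nCells = 250L, nFrames = 60L,
                           nPlantedEvents = c(up = 3, down = 3),
                           rngSeed = 7L)
    emb <- generateEmbryo(cfg)
    graphs <- buildNeighborhoodGraphs(emb$tracks)
    .fixtureCache$small <- list(config = cfg, tracks = emb$tracks,
                                truth = emb$truth, graphs = graphs)
  }
  .fixtureCache$small
}

referenceFixture <- function() {
  if (is.null(.fixtureCache$reference)) {
    cfg <- syntheticConfig(nPlantedEvents = c(up = 20, down = 20),
                           rngSeed = 1L)
    emb <- generateEmbryo(cfg)
    graphs <- buildNeighborhoodGraphs(emb$tracks)
    low <- detectEvents(emb$tracks, graphs,
                        params = detectionParams(scoreThreshold = 0.70))
    .fixtureCache$reference <- list(config = cfg, tracks = emb$tracks,
                                    truth = emb$truth, graphs = graphs,
                                    candidates = low)
  }
  .fixtureCache$reference
}

# Monte-Carlo contact-area oracle, independent of the face construction:
# samples points uniformly on the bisector-plane disc of a seed pair and
# classifies each by nearest seed within the cap sphere.
mcContactArea <- function(pts, i, j, capRadius = 20, nSample = 2e5) {
  d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  rho2 <- capRadius^2 - (d / 2)^2
  if (rho2 <= 0) return(0)
  m <- (pts[i, ] + pts[j, ]) / 2
  nrm <- (pts[j, ] - pts[i, ]) / d
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2], nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  r <- sqrt(rho2 * runif(nSample))
  th <- runif(nSample, 0, 2 * pi)
  X <- cbind(m[1] + r * cos(th) * e1[1] + r * sin(th) * e2[1],
             m[2] + r * cos(th) * e1[2] + r * sin(th) * e2[2],
             m[3] + r * cos(th) * e1[3] + r * sin(th) * e2[3])
  D2 <- lapply(seq_len(nrow(pts)), function(q)
    (X[, 1] - pts[q, 1])^2 + (X[, 2] - pts[q, 2])^2 +
    (X[, 3] - pts[q, 3])^2)
  inFace <- D2[[i]] <= Reduce(pmin, D2) + 1e-12
  mean(inFace) * pi * rho2
}

rotationMatrix3 <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

translateTracks <- function(tracks, shift) {
  d <- tracksData(tracks)
  d$x_um <- d$x_um + shift[1]
  d$y_um <- d$y_um + shift[2]
  d$z_um <- d$z_um + shift[3]
  CellTracks(d, frameInterval = frameInterval(tracks))
}

transformTracks <- function(tracks, R) {
  d <- tracksData(tracks)
  P <- as.matrix(d[, c("x_um", "y_um", "z_um")]) %*% t(R)
  d$x_um <- P[, 1]; d$y_um <- P[, 2]; d$z_um <- P[, 3]
  CellTracks(d, frameInterval = frameInterval(tracks))
}

# brute-force two-sided rank-sum p-value by direct enumeration over all
# assignments of the pooled midranks; tie-free cases are additionally
# cross-checked against stats::wilcox.test elsewhere in the suite
bruteWilcoxon <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  rk <- rank(c(a, b))
  stat <- function(idx) sum(rk[idx])
  obs <- stat(seq_len(n1))
  mu <- n1 * (n + 1) / 2
  all <- combn(n, n1, stat)
  mean(abs(all - mu) >= abs(obs - mu) - 1e-9)
}
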