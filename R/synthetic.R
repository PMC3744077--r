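#' Synthetic embryo configuration
#'
#' Parameters of the seeded synthetic-embryo generator: a hemispherical
#' blastoderm cap with an EVL monolayer and several deep-cell levels of
#' one cell diameter each (early gastrulae carry about six to eight levels
#' of blastomeres), recorded over ~two hours at the acquisition frame
#' interval. Ground-truth intercalation events following the three-stage
#' template are planted at known triples, windows and directions.
#'
#' @param nCells approximate total number of nuclei (default 400).
#' @param nFrames number of frames (default 120, about 126 min at the
#'   default interval).
#' @param frameInterval minutes per frame (default 1.05).
#' @param embryoRadius EVL sphere radius in micrometres (default 115;
#'   scaled-down embryo so a few hundred nuclei fill the cap at a
#'   realistic spacing).
#' @param capHalfAngle polar half-angle of the simulated blastoderm cap in
#'   degrees (default 60).
#' @param dclLevels number of deep-cell levels below the EVL (default 6).
#' @param cellSpacing typical nearest-neighbor distance / level thickness
#'   in micrometres (default 16).
#' @param noiseSigma per-frame isotropic positional jitter in micrometres
#'   (default 0.5, the order of nucleus-centroid localisation error in
#'   confocal tracking).
#' @param nPlantedEvents named counts of planted events per direction
#'   class, e.g. \code{c(up = 20, down = 20, lateral = 0)}.
#' @param plantDisplacement planted center-cell displacement in
#'   micrometres (default 16, about one cell diameter).
#' @param eventDuration planted event duration in frames (default 12).
#' @param mitosisGapRate per-track per-frame probability of a
#'   mitosis-like tracking gap: the track terminates and a new track id
#'   resumes after 1-2 missing frames (default 0.002).
#' @param doming when TRUE the deep-cell layer thins linearly over the
#'   recording (default FALSE: static geometry for unit testing).
#' @param domingThinning fractional DCL thinning at the last frame when
#'   \code{doming} is on (default 0.25).
#' @param rngSeed integer seed; all generator randomness derives from it.
#' @return Validated configuration list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nCells = 400L, nFrames = 120L,
                            frameInterval = 1.05, embryoRadius = 115,
                            capHalfAngle = 60, dclLevels = 6L,
                            cellSpacing = 16, noiseSigma = 0.5,
                            nPlantedEvents = c(up = 0L, down = 0L,
                                               lateral = 0L),
                            plantDisplacement = 16, eventDuration = 12L,
                            mitosisGapRate = 0.002, doming = FALSE,
                            domingThinning = 0.25, rngSeed = 1L) {
  full <- c(up = 0L, down = 0L, lateral = 0L)
  full[names(nPlantedEvents)] <- as.integer(nPlantedEvents)
  stopifnot(nCells > 0, nFrames > 0, frameInterval > 0, embryoRadius > 0,
            dclLevels > 0, cellSpacing > 0, noiseSigma >= 0,
            all(full >= 0), plantDisplacement > 0, eventDuration >= 4,
            mitosisGapRate >= 0, mitosisGapRate < 1,
            embryoRadius > (dclLevels + 1L) * cellSpacing)
  structure(list(nCells = as.integer(nCells), nFrames = as.integer(nFrames),
                 frameInterval = frameInterval, embryoRadius = embryoRadius,
                 capHalfAngle = capHalfAngle, dclLevels = as.integer(dclLevels),
                 cellSpacing = cellSpacing, noiseSigma = noiseSigma,
                 nPlantedEvents = full, plantDisplacement = plantDisplacement,
                 eventDuration = as.integer(eventDuration),
                 mitosisGapRate = mitosisGapRate, doming = doming,
                 domingThinning = domingThinning,
                 rngSeed = as.integer(rngSeed)),
            class = "SyntheticConfig")
}

# quasi-uniform points on a spherical cap (half-angle thetaMax, radius r)
.capLattice <- function(n, r, thetaMax) {
  if (n < 1L) return(matrix(numeric(0), 0, 3))
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  z <- 1 - (1 - cos(thetaMax)) * (i - 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * i
  r * cbind(rho * cos(phi), rho * sin(phi), z)
}

# orthonormal tangent vectors at unit direction u
.tangentBasis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- .unit(c(ref[2] * u[3] - ref[3] * u[2],
                ref[3] * u[1] - ref[1] * u[3],
                ref[1] * u[2] - ref[2] * u[1]))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2],
          u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  rbind(t1, t2)
}

#' Plant the center-cell path of one intercalation
#'
#' Moves the center cell k from its start position through the midplane of
#' its neighbors i and j onto their midpoint so that the six triple
#' features trace the three-stage template: the path is parameterised so
#' the enclosing angle w_k grows linearly in time from its start value to
#' 180 degrees (and hence w_i, w_j shrink linearly), while the Voronoi
#' contact a_ij collapses as k approaches the i-j axis. Optional Gaussian
#' jitter is added per frame.
#'
#' @param positions numeric 3 x 3 matrix, rows = positions of i, j and k
#'   (start) in micrometres; must form a non-degenerate triangle.
#' @param duration number of frames of the segment (>= 2).
#' @param noiseSigma per-frame isotropic jitter in micrometres.
#' @return Matrix (duration x 3): positions of k per frame; the last
#'   point is the i-j midpoint.
#' @export
plantIntercalation <- function(positions, duration, noiseSigma = 0) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == 3L, ncol(positions) == 3L, duration >= 2L)
  vi <- positions[1, ] - positions[3, ]
  vj <- positions[2, ] - positions[3, ]
  crs <- c(vi[2] * vj[3] - vi[3] * vj[2], vi[3] * vj[1] - vi[1] * vj[3],
           vi[1] * vj[2] - vi[2] * vj[1])
  if (sqrt(sum(crs^2)) < 1e-6)
    stop("degenerate (collinear) start triple")
  mid <- (positions[1, ] + positions[2, ]) / 2
  eIJ <- .unit(positions[2, ] - positions[1, ])
  a <- sqrt(sum((positions[2, ] - positions[1, ])^2)) / 2
  off <- positions[3, ] - mid
  along <- sum(off * eIJ)                 # component along the i-j axis
  perp <- off - along * eIJ               # height above the i-j axis
  h0 <- sqrt(sum(perp^2))
  nPerp <- perp / h0
  w0 <- 2 * atan2(a, h0)                  # start angle w_k in radians
  u <- seq(0, 1, length.out = duration)
  wk <- w0 + (pi - w0) * u                # linear angle transition
  h <- ifelse(u < 1, a / tan(wk / 2), 0)
  path <- matrix(mid, duration, 3, byrow = TRUE) +
    outer(h, nPerp) + outer((1 - u) * along, eIJ)
  if (noiseSigma > 0)
    path <- path + matrix(rnorm(3 * duration, sd = noiseSigma), duration, 3)
  path
}

#' Generate a synthetic embryo with planted ground truth
#'
#' Builds a static (optionally doming) hemispherical-cap blastoderm of
#' quasi-uniformly spaced nuclei -- an EVL monolayer above
#' \code{dclLevels} deep-cell levels of one cell spacing each -- and
#' simulates per-frame trajectories: non-event nuclei jitter around their
#' lattice position, planted center cells additionally execute the
#' three-stage intercalation motion between two dedicated neighbors, and
#' mitosis-like gaps terminate tracks and resume them under a new id
#' after 1-2 missing frames. Deterministic given the configuration seed.
#'
#' @param config a \code{\link{syntheticConfig}} list.
#' @return List with \code{tracks} (a \linkS4class{CellTracks}) and
#'   \code{truth} (data.frame: \code{event_id, center_track, neighbor_a,
#'   neighbor_b, frame_start, frame_end, direction, dx_um, dy_um,
#'   dz_um}).
#' @export
generateEmbryo <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$rngSeed)
  R <- config$embryoRadius
  sp <- config$cellSpacing
  thetaMax <- config$capHalfAngle * pi / 180
  L <- config$dclLevels
  radii <- R - sp * (0:L)           # level 0 = EVL
  radii <- radii[radii > sp]
  weights <- radii^2 / sum(radii^2)
  counts <- pmax(1L, round(config$nCells * weights))
  base <- do.call(rbind, lapply(seq_along(radii), function(ii) {
    P <- .capLattice(counts[ii], radii[ii], thetaMax)
    if (ii > 1L)  # placement jitter for deep cells, EVL stays spherical
      P <- P + matrix(rnorm(length(P), sd = sp / 12), nrow(P), 3)
    P
  }))
  isEVL <- rep(seq_along(radii) == 1L, counts)

  # ---- choose planted event sites (spatially separated triples)
  nEv <- config$nPlantedEvents
  dirs <- rep(names(nEv), nEv)
  disp <- config$plantDisplacement
  dur <- config$eventDuration
  if (length(dirs) && config$nFrames < dur + 8L)
    stop("recording too short for the requested planted events")
  # Sites must not collide in space; sites whose event windows overlap in
  # time additionally keep a wide berth so concurrent insertions never
  # perturb each other's triple features.
  sites <- list()
  centers <- matrix(numeric(0), 0, 3)
  windows <- matrix(integer(0), 0, 2)
  for (dd in dirs) {
    placed <- FALSE
    for (try in seq_len(20000L)) {
      ct <- runif(1, cos(max(thetaMax - 10 * pi / 180, 0.05)), 1)
      st <- sqrt(1 - ct^2)
      ph <- runif(1, 0, 2 * pi)
      u0 <- c(st * cos(ph), st * sin(ph), ct)
      # plant within the first few DCL levels, where intercalations
      # concentrate in embryos and where the lattice has regular spacing
      lmax_m <- min(length(radii) - 2L, 3L)
      pick <- function(x) x[sample.int(length(x), 1L)]
      lev <- switch(dd,
        up = pick(seq(1L, lmax_m)),
        down = pick(seq(2L, lmax_m + 1L)),
        lateral = pick(seq(1L, lmax_m)))
      rm_ <- R - sp * lev
      mPos <- rm_ * u0
      f0 <- sample.int(config$nFrames - dur - 6L, 1L) + 2L  # 0-based start
      if (nrow(centers)) {
        dd3 <- sqrt(rowSums(sweep(centers, 2, mPos)^2))
        concurrent <- windows[, 1] <= (f0 + dur + 2L) &
                      windows[, 2] >= (f0 - 3L)
        if (min(dd3) < 1.15 * sp ||
            (any(concurrent) && min(dd3[concurrent]) < 2.2 * sp)) next
      }
      tb <- .tangentBasis(u0)
      pi_ <- mPos + (sp / 2) * tb[1, ]
      pj_ <- mPos - (sp / 2) * tb[1, ]
      k0 <- switch(dd,
        up = mPos - disp * u0,       # starts deeper, moves toward the EVL
        down = mPos + disp * u0,     # starts nearer the EVL, moves inward
        lateral = mPos - disp * tb[2, ])
      sites[[length(sites) + 1L]] <-
        list(direction = dd, i = pi_, j = pj_, k0 = k0, k1 = mPos,
             f0 = f0, f1 = f0 + dur - 1L)
      centers <- rbind(centers, mPos)
      windows <- rbind(windows, c(f0, f0 + dur - 1L))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cannot place ", sum(nEv), " non-overlapping planted events; ",
           "reduce nPlantedEvents or enlarge the embryo")
  }

  # ---- carve out lattice cells colliding with planted triples
  if (length(sites)) {
    keyPts <- do.call(rbind, lapply(sites, function(s) {
      u <- seq(0, 1, length.out = 5)
      rbind(s$i, s$j, outer(1 - u, s$k0) + outer(u, s$k1))
    }))
    minD <- apply(base, 1L, function(p)
      min(sqrt(colSums((t(keyPts) - p)^2))))
    keep <- minD > 0.8 * sp
    base <- base[keep, , drop = FALSE]
    isEVL <- isEVL[keep]
  }

  nBase <- nrow(base)
  nFr <- config$nFrames
  fr <- 0:(nFr - 1L)
  thin <- if (config$doming)
    1 - config$domingThinning * fr / max(nFr - 1L, 1L) else rep(1, nFr)

  jitter <- function(n) matrix(rnorm(n * 3, sd = config$noiseSigma), n, 3)
  domify <- function(P, f) {
    # radial DCL compression toward the EVL sphere (doming/thinning)
    if (!config$doming) return(P)
    r <- sqrt(rowSums(P^2))
    rNew <- R - (R - r) * thin[f + 1L]
    P * (rNew / r)
  }

  rows <- vector("list", nBase + 3L * length(sites))
  tid <- 0L
  for (b in seq_len(nBase)) {
    tid <- tid + 1L
    P <- matrix(base[b, ], nFr, 3, byrow = TRUE)
    if (!isEVL[b]) for (f in fr) P[f + 1L, ] <- domify(P[f + 1L, , drop = FALSE], f)
    P <- P + jitter(nFr)
    rows[[tid]] <- data.frame(track_id = tid, frame = fr, x_um = P[, 1],
                              y_um = P[, 2], z_um = P[, 3],
                              is_evl = isEVL[b])
  }
  truth <- NULL
  for (s in sites) {
    idI <- tid + 1L; idJ <- tid + 2L; idK <- tid + 3L; tid <- tid + 3L
    for (who in c("i", "j")) {
      P <- matrix(s[[who]], nFr, 3, byrow = TRUE) + jitter(nFr)
      rows[[if (who == "i") idI else idJ]] <-
        data.frame(track_id = if (who == "i") idI else idJ, frame = fr,
                   x_um = P[, 1], y_um = P[, 2], z_um = P[, 3],
                   is_evl = FALSE)
    }
    P <- matrix(s$k0, nFr, 3, byrow = TRUE)
    during <- s$f0:s$f1
    P[during + 1L, ] <- plantIntercalation(rbind(s$i, s$j, s$k0),
                                           length(during), noiseSigma = 0)
    if (s$f1 + 1L < nFr)
      P[(s$f1 + 2L):nFr, ] <- matrix(s$k1, nFr - s$f1 - 1L, 3, byrow = TRUE)
    P <- P + jitter(nFr)
    rows[[idK]] <- data.frame(track_id = idK, frame = fr, x_um = P[, 1],
                              y_um = P[, 2], z_um = P[, 3], is_evl = FALSE)
    truth <- rbind(truth, data.frame(
      event_id = 0L,
      center_track = idK, neighbor_a = idI, neighbor_b = idJ,
      frame_start = s$f0, frame_end = s$f1, direction = s$direction,
      dx_um = s$k1[1] - s$k0[1], dy_um = s$k1[2] - s$k0[2],
      dz_um = s$k1[3] - s$k0[3]))
  }
  if (is.null(truth))
    truth <- data.frame(event_id = integer(0), center_track = integer(0),
                        neighbor_a = integer(0), neighbor_b = integer(0),
                        frame_start = integer(0), frame_end = integer(0),
                        direction = character(0), dx_um = numeric(0),
                        dy_um = numeric(0), dz_um = numeric(0))

  d <- do.call(rbind, rows)
  rm(rows)

  # ---- mitosis-like tracking gaps on non-event tracks
  if (config$mitosisGapRate > 0) {
    eventIds <- unique(c(truth$center_track, truth$neighbor_a,
                         truth$neighbor_b))
    nextId <- max(d$track_id) + 1L
    pieces <- split(d, d$track_id)
    for (nm in names(pieces)) {
      p <- pieces[[nm]]
      if (p$track_id[1] %in% eventIds || nrow(p) < 12L) next
      nSplit <- rbinom(1L, nrow(p) - 8L, config$mitosisGapRate)
      if (!nSplit) next
      at <- sort(sample(4:(nrow(p) - 4L), min(nSplit, 2L)))
      drop <- integer(0)
      newId <- p$track_id
      for (a in at) {
        g <- sample(1:2, 1L)
        drop <- c(drop, a:min(a + g - 1L, nrow(p)))
        after <- seq_len(nrow(p)) > a
        newId[after] <- nextId
        nextId <- nextId + 1L
      }
      p$track_id <- newId
      pieces[[nm]] <- p[-unique(drop), , drop = FALSE]
    }
    d <- do.call(rbind, pieces)
  }
  truth$event_id <- seq_len(nrow(truth))
  list(tracks = CellTracks(d, frameInterval = config$frameInterval),
       truth = truth)
}

#' Write a trajectory fixture and its ground truth
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @param truth ground-truth data.frame from \code{\link{generateEmbryo}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of the two CSV files written.
#' @export
writeFixture <- function(tracks, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fTracks <- file.path(dir, "tracks.csv")
  fTruth <- file.path(dir, "truth.csv")
  write.csv(tracksData(tracks), fTracks, row.names = FALSE, quote = FALSE)
  write.csv(truth, fTruth, row.names = FALSE, quote = FALSE)
  invisible(c(tracks = fTracks, truth = fTruth))
}

#' Read a trajectory table from CSV
#'
#' Expects the columns \code{track_id, frame, x_um, y_um, z_um} and
#' optionally \code{is_evl}; frames are 0-based, positions in micrometres.
#'
#' @param path CSV file path.
#' @param frameInterval minutes per frame (default 1.05).
#' @return A \linkS4class{CellTracks} object.
#' @export
readTracks <- function(path, frameInterval = 1.05) {
  CellTracks(read.csv(path), frameInterval = frameInterval)
}

#' Read a planted-event ground-truth table from CSV
#'
#' @param path CSV file path as written by \code{\link{writeFixture}}.
#' @return data.frame of planted events.
#' @export
readGroundTruth <- function(path) read.csv(path)

#' Match detected events against planted ground truth
#'
#' A detected event matches a planted one when it has the same center
#' cell, the same unordered neighbor pair and a time window overlapping
#' the planted window. Sensitivity is the fraction of planted events
#' recovered; the false discovery rate is the fraction of detections
#' matching no planted event.
#'
#' @param events data.frame from \code{\link{detectEvents}}.
#' @param truth ground-truth data.frame.
#' @return List with \code{sensitivity}, \code{fdr}, \code{nMatched},
#'   \code{matchedTruth} (logical per truth row) and \code{matchedEvent}
#'   (index of the matched truth row per event, NA for false positives).
#' @export
matchGroundTruth <- function(events, truth) {
  matchedTruth <- logical(nrow(truth))
  matchedEvent <- rep(NA_integer_, nrow(events))
  if (nrow(events) && nrow(truth)) {
    for (r in seq_len(nrow(events))) {
      pair <- sort(c(events$neighbor_a[r], events$neighbor_b[r]))
      hit <- which(truth$center_track == events$center[r] &
                   pmin(truth$neighbor_a, truth$neighbor_b) == pair[1] &
                   pmax(truth$neighbor_a, truth$neighbor_b) == pair[2] &
                   truth$frame_start <= events$frame_end[r] &
                   truth$frame_end >= events$frame_start[r])
      if (length(hit)) {
        matchedTruth[hit[1]] <- TRUE
        matchedEvent[r] <- hit[1]
      }
    }
  }
  list(sensitivity = if (nrow(truth)) mean(matchedTruth) else NA_real_,
       fdr = if (nrow(events)) mean(is.na(matchedEvent)) else NA_real_,
       nMatched = sum(matchedTruth), matchedTruth = matchedTruth,
       matchedEvent = matchedEvent)
}
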