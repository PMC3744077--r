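.dirLevels <- c("up", "down", "lateral")

.poissonCI <- function(n, exact = FALSE) {
  if (exact) {
    lo <- ifelse(n == 0, 0, qchisq(0.025, 2 * n) / 2)
    hi <- qchisq(0.975, 2 * (n + 1)) / 2
  } else {
    lo <- pmax(0, n - 1.96 * sqrt(n))
    hi <- n + 1.96 * sqrt(n)
  }
  cbind(lower = lo, upper = hi)
}

#' Direction counts, ratios and Poisson confidence intervals
#'
#' Counts verified events per direction class, with 95\% confidence
#' intervals assuming Poisson noise (normal approximation N +/- 1.96
#' sqrt(N), clipped at 0; exact Garwood intervals on request) and the two
#' headline ratios: upward to downward events, and lateralward to radial
#' (up + down) events. Undefined ratios (zero denominator) are NA.
#'
#' @param events annotated events data.frame; only rows with
#'   \code{verified == TRUE} are counted (all rows when the column is
#'   absent).
#' @param exactCI use exact Garwood intervals instead of the normal
#'   approximation (default FALSE).
#' @return List with \code{counts} (named integer), \code{ci} (matrix),
#'   \code{ratios} (named numeric: \code{up_down}, \code{lateral_radial}).
#' @export
countSummary <- function(events, exactCI = FALSE) {
  if (nrow(events) && "verified" %in% names(events))
    events <- events[events$verified, , drop = FALSE]
  counts <- table(factor(events$direction, levels = .dirLevels))
  counts <- stats::setNames(as.integer(counts), .dirLevels)
  nUp <- counts[["up"]]; nDown <- counts[["down"]]
  nLat <- counts[["lateral"]]
  ratios <- c(up_down = if (nDown > 0) nUp / nDown else NA_real_,
              lateral_radial = if (nUp + nDown > 0)
                nLat / (nUp + nDown) else NA_real_)
  list(counts = counts, ci = .poissonCI(counts, exactCI), ratios = ratios)
}

#' Depth profile of intercalation rates
#'
#' Events per direction in each half-diameter depth bin, normalised by the
#' number of (cell, frame) observations at that depth, so that levels with
#' different cell occupancy are comparable. Depths beyond \code{maxDepth}
#' cell diameters are truncated (too few events to be informative).
#'
#' @param events annotated events data.frame (verified rows are used).
#' @param tracks a \linkS4class{CellTracks} object.
#' @param surface an \linkS4class{EVLSurface}.
#' @param d reference cell diameter in micrometres.
#' @param binWidth bin width in cell diameters (default 0.5).
#' @param maxDepth profile truncation depth in diameters (default 4).
#' @return data.frame with columns \code{depth_lo, depth_hi, direction,
#'   n_events, n_observations, rate}.
#' @export
depthProfile <- function(events, tracks, surface, d = 16.1095,
                         binWidth = 0.5, maxDepth = 4) {
  breaks <- seq(0, maxDepth, by = binWidth)
  pa <- .positionArray(tracks)
  obs <- integer(length(breaks) - 1L)
  for (f in 0:(pa$nFrames - 1L)) {
    present <- which(is.finite(pa$X[, f + 1L]))
    if (!length(present)) next
    P <- cbind(pa$X[present, f + 1L], pa$Y[present, f + 1L],
               pa$Z[present, f + 1L])
    dep <- depthOf(P, surface, f, d)
    h <- findInterval(dep, breaks, rightmost.closed = FALSE)
    h <- h[dep >= 0 & dep < maxDepth]
    obs <- obs + tabulate(h, nbins = length(obs))
  }
  if (nrow(events) && "verified" %in% names(events))
    events <- events[events$verified, , drop = FALSE]
  out <- expand.grid(bin = seq_len(length(breaks) - 1L),
                     direction = .dirLevels, stringsAsFactors = FALSE)
  out$depth_lo <- breaks[out$bin]
  out$depth_hi <- breaks[out$bin + 1L]
  out$n_events <- 0L
  if (nrow(events)) {
    h <- findInterval(events$depth_diam, breaks, rightmost.closed = FALSE)
    okRow <- events$depth_diam >= 0 & events$depth_diam < maxDepth
    for (r in which(okRow)) {
      hit <- out$bin == h[r] & out$direction == events$direction[r]
      out$n_events[hit] <- out$n_events[hit] + 1L
    }
  }
  out$n_observations <- obs[out$bin]
  out$rate <- ifelse(out$n_observations > 0,
                     out$n_events / out$n_observations, NA_real_)
  out[order(out$direction, out$bin), c("depth_lo", "depth_hi", "direction",
                                       "n_events", "n_observations",
                                       "rate")]
}

#' Intercalation history tree
#'
#' Successive intercalations of individual center cells, up to
#' \code{maxDepth} events per cell: the root counts all cells performing a
#' first event; each node branches by the direction of the next event and
#' carries the absolute count and the fraction of its parent.
#'
#' @param events annotated events data.frame (verified rows are used).
#' @param maxDepth maximum number of successive events (default 3).
#' @return data.frame with columns \code{depth} (1 = first event),
#'   \code{path} (directions joined by "/"), \code{count} and
#'   \code{fraction} (of the parent node; 1 for depth-1 total).
#' @export
historyTree <- function(events, maxDepth = 3L) {
  if (nrow(events) && "verified" %in% names(events))
    events <- events[events$verified, , drop = FALSE]
  if (!nrow(events))
    return(data.frame(depth = integer(0), path = character(0),
                      count = integer(0), fraction = numeric(0)))
  ord <- order(events$center, events$frame_start_rev %||% events$frame_start)
  ev <- events[ord, ]
  seqs <- lapply(split(ev$direction, ev$center), function(x)
    x[seq_len(min(length(x), maxDepth))])
  paths <- unlist(lapply(seqs, function(s)
    vapply(seq_along(s), function(k) paste(s[seq_len(k)], collapse = "/"),
           character(1))))
  tab <- table(paths)
  out <- data.frame(path = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$depth <- lengths(strsplit(out$path, "/", fixed = TRUE))
  parentCount <- function(p, dep) {
    if (dep == 1L) return(sum(out$count[out$depth == 1L]))
    pp <- sub("/[^/]+$", "", p)
    out$count[out$path == pp]
  }
  out$fraction <- vapply(seq_len(nrow(out)), function(r)
    out$count[r] / parentCount(out$path[r], out$depth[r]), numeric(1))
  out[order(out$depth, out$path), c("depth", "path", "count", "fraction")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sector exit to radial intercalation ratio
#'
#' Per analysis window: the number of cells located in the inner sector S1
#' at the window start and outside it at the window end, divided by the
#' number of radial (up + down) intercalations starting in S1 during the
#' window. Windows without radial events yield NA.
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @param events annotated events data.frame (verified rows are used).
#' @param surface an \linkS4class{EVLSurface}.
#' @param halfAngle S1 half-angle in degrees (default 45).
#' @param windowMinutes window length in minutes (default 15).
#' @return data.frame with columns \code{t_lo, t_hi, n_exits, n_radial,
#'   ratio}.
#' @export
sectorExitRatio <- function(tracks, events, surface, halfAngle = 45,
                            windowMinutes = 15) {
  if (nrow(events) && "verified" %in% names(events))
    events <- events[events$verified, , drop = FALSE]
  pa <- .positionArray(tracks)
  dt <- frameInterval(tracks)
  tEnd <- (pa$nFrames - 1L) * dt
  edges <- seq(0, tEnd, by = windowMinutes)
  if (edges[length(edges)] < tEnd) edges <- c(edges, tEnd)
  out <- NULL
  for (w in seq_len(length(edges) - 1L)) {
    f0 <- ceiling(edges[w] / dt)
    f1 <- floor(edges[w + 1L] / dt)
    inS1 <- function(f) {
      present <- which(is.finite(pa$X[, f + 1L]))
      P <- cbind(pa$X[present, f + 1L], pa$Y[present, f + 1L],
                 pa$Z[present, f + 1L])
      stats::setNames(assignSector(P, surface, f, halfAngle) == "S1",
                      pa$ids[present])
    }
    s0 <- inS1(f0); s1 <- inS1(f1)
    both <- intersect(names(s0)[s0], names(s1))
    nExit <- sum(!s1[both])
    fs <- events$frame_start_rev %||% events$frame_start
    inWin <- fs >= f0 & fs < f1
    nRad <- sum(inWin & events$direction %in% c("up", "down") &
                events$sector == "S1")
    out <- rbind(out, data.frame(t_lo = edges[w], t_hi = edges[w + 1L],
                                 n_exits = nExit, n_radial = nRad,
                                 ratio = if (nRad > 0) nExit / nRad
                                         else NA_real_))
  }
  out
}

#' Run the full intercalation analysis pipeline
#'
#' Executes tessellation, template-based detection, local-motion
#' refinement, verification, anatomical classification, directionality
#' expansion and summary aggregation on a trajectory table, returning an
#' \linkS4class{IntercalationReport}. Deterministic given its inputs.
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @param detection a \code{\link{detectionParams}} list.
#' @param anatomy an \code{\link{anatomyParams}} list, or NULL to use the
#'   dataset's own median nearest-neighbor diameter as reference cell
#'   diameter.
#' @param template optional \linkS4class{IntercalationTemplate}.
#' @param lmax spherical-harmonics degree for the directionality
#'   expansion (default 10).
#' @param verbose log per-stage progress to stderr (default FALSE).
#' @return An \linkS4class{IntercalationReport}.
#' @export
runPipeline <- function(tracks, detection = detectionParams(),
                        anatomy = NULL, template = NULL, lmax = 10L,
                        verbose = FALSE) {
  stopifnot(is(tracks, "CellTracks"))
  say <- function(...) if (verbose) message("[intercalR] ", ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("%s: %.1f s", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  if (is.null(anatomy)) {
    d <- stage("cell diameter", nearestNeighborDiameter(tracks))
    anatomy <- anatomyParams(cellDiameter = d,
                             lateralHalfWidth = min(7, 0.435 * d))
  }
  graphs <- stage("voronoi",
                  buildNeighborhoodGraphs(tracks,
                                          capRadius = detection$capRadius))
  events <- stage("detect", detectEvents(tracks, graphs, template, detection))
  events <- stage("motion", computeKinematics(tracks, events))
  events <- stage("verify", verifyEvents(events))
  surface <- stage("evl surface", fitEVLSurface(tracks))
  events <- stage("anatomy", annotateEvents(events, tracks, surface, anatomy))
  ver <- events[which(events$verified), , drop = FALSE]
  coefs <- data.frame(l = integer(0), m = integer(0), c = numeric(0))
  c20 <- NA_real_
  if (nrow(ver)) {
    vecs <- as.matrix(ver[, c("dx", "dy", "dz")])
    ax <- animalAxis(surface, surface@frames[1])
    coefs <- stage("directionality",
                   shExpand(toAnatomicalFrame(vecs, ax), lmax = lmax))
    c20 <- polarityC20(coefs)
  }
  summ <- stage("summaries", {
    cs <- countSummary(events)
    list(counts = cs$counts, ci = cs$ci, ratios = cs$ratios, c20 = c20,
         depthProfile = depthProfile(events, tracks, surface,
                                     anatomy$cellDiameter),
         historyTree = historyTree(events),
         sectorExit = sectorExitRatio(tracks, events, surface,
                                      anatomy$sectorHalfAngle),
         kinematics = if (nrow(ver)) data.frame(
           median_eff_speed = median(ver$eff_speed_um_min),
           median_inst_speed = median(ver$inst_speed_um_min),
           median_abs_disp = median(ver$abs_disp_um),
           median_path_len = median(ver$path_len_um)) else NULL)
  })
  new("IntercalationReport", events = events, summary = summ,
      coefficients = coefs,
      params = list(detection = detection, anatomy = anatomy))
}

#' Write report tables to CSV
#'
#' @param report an \linkS4class{IntercalationReport}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.csv"),
             coefficients = file.path(dir, "sh_coefficients.csv"),
             depth = file.path(dir, "depth_profile.csv"),
             history = file.path(dir, "history_tree.csv"),
             sector = file.path(dir, "sector_exit.csv"))
  write.csv(report@events, paths["events"], row.names = FALSE)
  write.csv(report@coefficients, paths["coefficients"], row.names = FALSE)
  write.csv(report@summary$depthProfile, paths["depth"], row.names = FALSE)
  write.csv(report@summary$historyTree, paths["history"], row.names = FALSE)
  write.csv(report@summary$sectorExit, paths["sector"], row.names = FALSE)
  invisible(paths)
}
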