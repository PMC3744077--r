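#' Tissue-relative path of a cell
#'
#' Compensates translational tissue motion by successive temporal
#' registration of the cell's local group: at every frame step the mean
#' displacement of the \code{kNeighbors} nearest cells within
#' \code{radius} of the cell (the cell itself excluded) is subtracted from
#' the cell's displacement, and the relative steps are accumulated into a
#' path starting at the origin. If the local group is empty at some step,
#' the global mean displacement of all other cells is used instead.
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @param cell track id of the moving cell.
#' @param window integer length-2, 0-based first and last frame.
#' @param kNeighbors local group size (default 10).
#' @param radius local group search radius in micrometres (default 40).
#' @return data.frame with columns \code{frame, x, y, z}: the relative
#'   path (micrometres, starting at the origin).
#' @export
registerLocal <- function(tracks, cell, window, kNeighbors = 10L,
                          radius = 40) {
  pa <- .positionArray(tracks)
  rk <- match(cell, pa$ids)
  if (is.na(rk)) stop("unknown track id: ", cell)
  frames <- seq(window[1], window[2])
  cols <- frames + 1L
  if (anyNA(pa$X[rk, cols])) stop("cell not tracked throughout the window")
  n <- length(frames)
  path <- matrix(0, n, 3)
  for (t in seq_len(n - 1L)) {
    c0 <- cols[t]; c1 <- cols[t + 1L]
    stepK <- c(pa$X[rk, c1] - pa$X[rk, c0], pa$Y[rk, c1] - pa$Y[rk, c0],
               pa$Z[rk, c1] - pa$Z[rk, c0])
    present <- which(is.finite(pa$X[, c0]) & is.finite(pa$X[, c1]))
    present <- setdiff(present, rk)
    ref <- c(0, 0, 0)
    if (length(present)) {
      dx <- pa$X[present, c0] - pa$X[rk, c0]
      dy <- pa$Y[present, c0] - pa$Y[rk, c0]
      dz <- pa$Z[present, c0] - pa$Z[rk, c0]
      dist <- sqrt(dx^2 + dy^2 + dz^2)
      grp <- present[dist <= radius]
      if (length(grp) > kNeighbors)
        grp <- grp[order(dist[dist <= radius])[seq_len(kNeighbors)]]
      if (!length(grp)) grp <- present  # fall back to global registration
      ref <- c(mean(pa$X[grp, c1] - pa$X[grp, c0]),
               mean(pa$Y[grp, c1] - pa$Y[grp, c0]),
               mean(pa$Z[grp, c1] - pa$Z[grp, c0]))
    }
    path[t + 1L, ] <- path[t, ] + (stepK - ref)
  }
  data.frame(frame = frames, x = path[, 1], y = path[, 2], z = path[, 3])
}

.pathMatrix <- function(path) {
  P <- as.matrix(path[, c("x", "y", "z")])
  if (!all(is.finite(P))) stop("path contains non-finite positions")
  P
}

#' Main motion direction of a path
#'
#' First principal axis of the mean-centered path points (the 3D line of
#' best fit), with the sign chosen so the direction points from the
#' extremal path point reached earlier to the one reached later.
#'
#' @param path data.frame with columns \code{x, y, z} (micrometres).
#' @return List with \code{direction} (unit 3-vector) and
#'   \code{eigenvalues} (covariance eigenvalues, decreasing).
#' @export
mainDirection <- function(path) {
  P <- .pathMatrix(path)
  if (nrow(unique(P)) < 2L) stop("path needs at least 2 distinct points")
  C <- cov(P)
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  proj <- as.vector(P %*% v)
  if (which.max(proj) < which.min(proj)) v <- -v
  list(direction = v, eigenvalues = pmax(eg$values, 0))
}

#' Refine an event path along its main direction
#'
#' The extremal points of the path's scalar projection onto the main
#' direction define the revised window; the effective displacement is the
#' path difference between the revised end and start points.
#'
#' @param path data.frame with columns \code{frame, x, y, z}.
#' @param direction unit 3-vector (see \code{\link{mainDirection}}).
#' @return List with \code{path} (the revised sub-path), \code{window}
#'   (0-based revised first/last frame), \code{displacement} (3-vector,
#'   micrometres).
#' @export
refineEvent <- function(path, direction) {
  P <- .pathMatrix(path)
  proj <- as.vector(P %*% .unit(direction))
  i0 <- which.min(proj); i1 <- which.max(proj)
  if (i0 == i1) stop("zero-extent path: projection has no extent")
  a <- min(i0, i1); b <- max(i0, i1)
  rev <- path[a:b, , drop = FALSE]
  list(path = rev, window = c(path$frame[a], path$frame[b]),
       displacement = unname(P[b, ] - P[a, ]))
}

#' Directedness of a path
#'
#' Ratio of the first eigenvalue of the path-point covariance to the sum
#' of eigenvalues: 1 for perfectly straight motion, 1/3 for an isotropic
#' 3D point cloud.
#'
#' @param path data.frame with columns \code{x, y, z}.
#' @return r_dir in [1/3, 1] (for paths with positive total variance).
#' @export
directedness <- function(path) {
  P <- .pathMatrix(path)
  if (nrow(unique(P)) < 2L) stop("path needs at least 2 distinct points")
  ev <- pmax(eigen(cov(P), symmetric = TRUE, only.values = TRUE)$values, 0)
  ev[1L] / sum(ev)
}

#' Kinematics of a revised event path
#'
#' @param path revised path data.frame (\code{frame, x, y, z}).
#' @param frameInterval minutes per frame (default 1.05).
#' @return List with \code{effective_displacement} (3-vector),
#'   \code{abs_displacement}, \code{path_length} (micrometres),
#'   \code{duration} (minutes), \code{effective_speed} and
#'   \code{instantaneous_speed} (micrometres per minute). The average
#'   instantaneous speed uses the full path length and is therefore never
#'   smaller than the effective speed. A single-step window has duration
#'   one frame interval.
#' @export
eventSpeeds <- function(path, frameInterval = 1.05) {
  P <- .pathMatrix(path)
  n <- nrow(P)
  duration <- max(n - 1L, 1L) * frameInterval
  disp <- unname(P[n, ] - P[1, ])
  absDisp <- sqrt(sum(disp^2))
  pathLen <- if (n > 1L) sum(sqrt(rowSums((P[-1, , drop = FALSE] -
                                           P[-n, , drop = FALSE])^2))) else 0
  list(effective_displacement = disp, abs_displacement = absDisp,
       path_length = pathLen, duration = duration,
       effective_speed = absDisp / duration,
       instantaneous_speed = pathLen / duration)
}

#' Compute relative motion and kinematics for detected events
#'
#' For every event: registers the center cell against its local tissue
#' (\code{\link{registerLocal}}), finds the main motion direction by PCA,
#' refines the window to the extremal points along that direction, and
#' derives directedness and speeds from the revised path.
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @param events data.frame from \code{\link{detectEvents}}.
#' @param kNeighbors,radius local registration group (see
#'   \code{\link{registerLocal}}).
#' @return The events data.frame with added columns \code{dx, dy, dz}
#'   (effective displacement, micrometres), \code{abs_disp_um},
#'   \code{r_dir}, \code{eff_speed_um_min}, \code{inst_speed_um_min},
#'   \code{path_len_um}, \code{frame_start_rev}, \code{frame_end_rev}.
#' @export
computeKinematics <- function(tracks, events, kNeighbors = 10L,
                              radius = 40) {
  cols <- c("dx", "dy", "dz", "abs_disp_um", "r_dir", "eff_speed_um_min",
            "inst_speed_um_min", "path_len_um")
  for (cn in cols) events[[cn]] <- NA_real_
  events$frame_start_rev <- NA_integer_
  events$frame_end_rev <- NA_integer_
  if (!nrow(events)) return(events)
  dt <- frameInterval(tracks)
  for (r in seq_len(nrow(events))) {
    path <- registerLocal(tracks, events$center[r],
                          c(events$frame_start[r], events$frame_end[r]),
                          kNeighbors = kNeighbors, radius = radius)
    md <- mainDirection(path)
    ref <- refineEvent(path, md$direction)
    sp <- eventSpeeds(ref$path, dt)
    events$dx[r] <- sp$effective_displacement[1]
    events$dy[r] <- sp$effective_displacement[2]
    events$dz[r] <- sp$effective_displacement[3]
    events$abs_disp_um[r] <- sp$abs_displacement
    events$r_dir[r] <- directedness(ref$path)
    events$eff_speed_um_min[r] <- sp$effective_speed
    events$inst_speed_um_min[r] <- sp$instantaneous_speed
    events$path_len_um[r] <- sp$path_length
    events$frame_start_rev[r] <- ref$window[1]
    events$frame_end_rev[r] <- ref$window[2]
  }
  events
}

#' Verify events by displacement and directedness
#'
#' Pure threshold filter: an event is kept exactly when its absolute
#' effective displacement is at least \code{minDisplacement} (about the
#' range of a cell diameter is expected for true intercalations) and its
#' directedness r_dir is at least \code{minDirectedness}. Events exactly
#' at a threshold are kept.
#'
#' @param events data.frame from \code{\link{computeKinematics}}.
#' @param minDisplacement micrometres (default 6).
#' @param minDirectedness dimensionless (default 0.85).
#' @return The events data.frame with an added logical column
#'   \code{verified}.
#' @export
verifyEvents <- function(events, minDisplacement = 6,
                         minDirectedness = 0.85) {
  events$verified <- if (nrow(events))
    events$abs_disp_um >= minDisplacement & events$r_dir >= minDirectedness
  else logical(0)
  events
}
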