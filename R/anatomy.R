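#' Anatomical classification parameters
#'
#' @param cellDiameter reference cell diameter d in micrometres, the
#'   median nearest-neighbor distance over all cells and frames (default
#'   16.1095, the value measured on the original embryo recordings; for
#'   other data use \code{\link{nearestNeighborDiameter}}).
#' @param lateralHalfWidth half-width of the lateral classification band
#'   in micrometres: events whose displacement component along the EVL
#'   normal is within +/- this value are lateralward (default 7, about
#'   0.43 d).
#' @param sectorHalfAngle half-angle (degrees) of the inner sector S1
#'   about the animal-vegetal axis (default 45; the sector geometry is a
#'   configurable stand-in).
#' @param timeWindowEdges increasing window boundaries in minutes
#'   (default 0, 42, 84, 126).
#' @param timeWindowLabels labels of the analysis time windows.
#' @return Named list of anatomy parameters.
#' @export
anatomyParams <- function(cellDiameter = 16.1095, lateralHalfWidth = 7,
                          sectorHalfAngle = 45,
                          timeWindowEdges = c(0, 42, 84, 126),
                          timeWindowLabels = c("T1", "T2", "T3")) {
  stopifnot(cellDiameter > 0, lateralHalfWidth > 0,
            lateralHalfWidth < cellDiameter,
            all(diff(timeWindowEdges) > 0),
            length(timeWindowLabels) == length(timeWindowEdges) - 1L)
  list(cellDiameter = cellDiameter, lateralHalfWidth = lateralHalfWidth,
       sectorHalfAngle = sectorHalfAngle, timeWindowEdges = timeWindowEdges,
       timeWindowLabels = timeWindowLabels)
}

#' Fit the EVL reference surface
#'
#' Per frame, fits a smooth near-spherical surface to the EVL-flagged
#' nuclei: a least-squares sphere plus a ridge-penalised
#' spherical-harmonics radial correction (degree at most \code{lmax}) of
#' the nuclei radii about the fitted center. The animal-vegetal axis is
#' the mean outward radial direction of the EVL nuclei (the EVL cap is
#' centered on the animal pole in these recordings).
#'
#' @param tracks a \linkS4class{CellTracks} object with EVL-flagged
#'   nuclei.
#' @param lmax spherical-harmonics degree of the radial correction
#'   (default 4).
#' @param lambda ridge penalty weight on the correction coefficients,
#'   scaled by (l(l+1))^2 (default 1e-2).
#' @param minPoints minimum EVL nuclei per frame (default 10).
#' @return An \linkS4class{EVLSurface}.
#' @export
fitEVLSurface <- function(tracks, lmax = 4L, lambda = 1e-2,
                          minPoints = 10L) {
  pa <- .positionArray(tracks)
  evlRows <- which(pa$isEVL)
  if (length(evlRows) < minPoints)
    stop("fewer than ", minPoints, " EVL-flagged tracks")
  nC <- (lmax + 1L)^2
  frames <- 0:(pa$nFrames - 1L)
  center <- matrix(NA_real_, length(frames), 3)
  radius <- numeric(length(frames))
  coef <- matrix(0, length(frames), nC)
  axis <- matrix(NA_real_, length(frames), 3)
  rms <- numeric(length(frames))
  ls <- .shDegrees(lmax)$l
  pen <- lambda * (ls * (ls + 1))^2
  for (f in seq_along(frames)) {
    col <- f
    ok <- evlRows[is.finite(pa$X[evlRows, col])]
    if (length(ok) < minPoints)
      stop("frame ", frames[f], ": fewer than ", minPoints, " EVL nuclei")
    P <- cbind(pa$X[ok, col], pa$Y[ok, col], pa$Z[ok, col])
    A <- cbind(2 * P, 1)
    qrA <- qr(A)
    if (qrA$rank < 4L)
      stop("frame ", frames[f], ": degenerate (coplanar) EVL nuclei")
    sol <- qr.coef(qrA, rowSums(P^2))
    ctr <- sol[1:3]
    R0 <- sqrt(max(sol[4] + sum(ctr^2), .Machine$double.eps))
    V <- sweep(P, 2, ctr)
    r <- sqrt(rowSums(V^2))
    U <- V / r
    theta <- acos(.clamp(U[, 3], -1, 1))
    phi <- atan2(U[, 2], U[, 1])
    Y <- .realSH(lmax, theta, phi)
    b <- solve(crossprod(Y) + diag(pen, nC), crossprod(Y, r - R0))
    res <- r - (R0 + Y %*% b)
    center[f, ] <- ctr
    radius[f] <- R0
    coef[f, ] <- b
    axis[f, ] <- .unit(colMeans(U))
    rms[f] <- sqrt(mean(res^2))
  }
  new("EVLSurface", frames = frames, center = center, radius = radius,
      coef = coef, lmax = as.integer(lmax), axis = axis, residualRMS = rms)
}

.frameIndex <- function(surface, frame) {
  fi <- match(frame, surface@frames)
  if (is.na(fi)) stop("surface not fitted for frame ", frame)
  fi
}

#' Surface radius along given directions
#'
#' @param surface an \linkS4class{EVLSurface}.
#' @param frame 0-based frame index.
#' @param dirs matrix (n x 3) of directions from the embryo center (need
#'   not be unit length).
#' @return Numeric vector of surface radii in micrometres.
#' @export
surfaceRadius <- function(surface, frame, dirs) {
  fi <- .frameIndex(surface, frame)
  dirs <- matrix(dirs, ncol = 3)
  U <- dirs / sqrt(rowSums(dirs^2))
  theta <- acos(.clamp(U[, 3], -1, 1))
  phi <- atan2(U[, 2], U[, 1])
  Y <- .realSH(surface@lmax, theta, phi)
  as.vector(surface@radius[fi] + Y %*% surface@coef[fi, ])
}

#' Signed depth below the EVL surface
#'
#' Distance from the surface measured along the radial coordinate,
#' positive inward (toward the deep cell layer interior), in micrometres.
#'
#' @param surface an \linkS4class{EVLSurface}.
#' @param frame 0-based frame index.
#' @param points matrix (n x 3) of positions in micrometres.
#' @return Numeric vector of signed depths.
#' @export
signedDepth <- function(surface, frame, points) {
  fi <- .frameIndex(surface, frame)
  points <- matrix(points, ncol = 3)
  V <- sweep(points, 2, surface@center[fi, ])
  r <- sqrt(rowSums(V^2))
  surfaceRadius(surface, frame, V) - r
}

#' Depth in cell diameters
#'
#' Continuous depth level of a point: the signed inward distance from the
#' EVL surface divided by the reference cell diameter. Depths are
#' discretised into half-diameter bins only at reporting time.
#'
#' @param points matrix (n x 3) of positions in micrometres.
#' @param surface an \linkS4class{EVLSurface}.
#' @param frame 0-based frame index.
#' @param d reference cell diameter in micrometres.
#' @return Numeric vector of depths in cell diameters (0 on the surface).
#' @export
depthOf <- function(points, surface, frame, d = 16.1095) {
  stopifnot(d > 0)
  signedDepth(surface, frame, points) / d
}

#' Outward unit normal of the EVL surface
#'
#' Numerical gradient of the implicit surface function (radial distance
#' minus surface radius), normalised; points away from the embryo center.
#'
#' @param surface an \linkS4class{EVLSurface}.
#' @param frame 0-based frame index.
#' @param points matrix (n x 3) of positions (typically near the surface).
#' @param h finite-difference step in micrometres.
#' @return Matrix (n x 3) of outward unit normals.
#' @export
surfaceNormal <- function(surface, frame, points, h = 0.5) {
  points <- matrix(points, ncol = 3)
  Fv <- function(P) -signedDepth(surface, frame, P)  # increases outward
  G <- matrix(0, nrow(points), 3)
  for (ax in 1:3) {
    Pp <- points; Pp[, ax] <- Pp[, ax] + h
    Pm <- points; Pm[, ax] <- Pm[, ax] - h
    G[, ax] <- (Fv(Pp) - Fv(Pm)) / (2 * h)
  }
  G / sqrt(rowSums(G^2))
}

#' Animal-vegetal axis of a fitted frame
#'
#' @param surface an \linkS4class{EVLSurface}.
#' @param frame 0-based frame index.
#' @return Unit 3-vector pointing toward the animal pole.
#' @name animalAxis
#' @export
setMethod("animalAxis", "EVLSurface", function(surface, frame) {
  surface@axis[.frameIndex(surface, frame), ]
})

#' Classify an intercalation direction
#'
#' An event is lateralward when the component of its effective
#' displacement along the outward EVL normal is within
#' +/- \code{lateralHalfWidth}; it is upward (toward the EVL) when the
#' component exceeds the band and downward when it falls below it.
#'
#' @param displacement effective displacement 3-vector in micrometres.
#' @param normal outward unit surface normal at the event start.
#' @param lateralHalfWidth micrometres (default 7).
#' @return One of \code{"up"}, \code{"down"}, \code{"lateral"}.
#' @export
classifyDirection <- function(displacement, normal, lateralHalfWidth = 7) {
  if (sqrt(sum(displacement^2)) < .Machine$double.eps)
    stop("zero-length displacement cannot be classified")
  cc <- sum(displacement * .unit(normal))
  if (abs(cc) <= lateralHalfWidth) "lateral" else if (cc > 0) "up" else "down"
}

#' Assign points to the inner or outer sector
#'
#' S1 is the cone of half-angle \code{halfAngle} about the animal-vegetal
#' axis (the central animal region); everything else is S2.
#'
#' @param points matrix (n x 3) of positions in micrometres.
#' @param surface an \linkS4class{EVLSurface}.
#' @param frame 0-based frame index.
#' @param halfAngle degrees (default 45).
#' @return Character vector of \code{"S1"}/\code{"S2"}.
#' @export
assignSector <- function(points, surface, frame, halfAngle = 45) {
  fi <- .frameIndex(surface, frame)
  points <- matrix(points, ncol = 3)
  V <- sweep(points, 2, surface@center[fi, ])
  U <- V / sqrt(rowSums(V^2))
  ang <- acos(.clamp(as.vector(U %*% surface@axis[fi, ]), -1, 1)) * 180 / pi
  ifelse(ang <= halfAngle, "S1", "S2")
}

#' Assign frames to analysis time windows
#'
#' Windows are half-open intervals [lo, hi) in minutes; the last window is
#' closed at its upper edge.
#'
#' @param frame 0-based frame index (vectorised).
#' @param frameInterval minutes per frame (default 1.05).
#' @param edges increasing window boundaries in minutes.
#' @param labels one label per window.
#' @return Character vector of window labels (NA outside the recording).
#' @export
assignTimeWindow <- function(frame, frameInterval = 1.05,
                             edges = c(0, 42, 84, 126),
                             labels = c("T1", "T2", "T3")) {
  stopifnot(length(labels) == length(edges) - 1L, all(diff(edges) > 0))
  minute <- frame * frameInterval
  idx <- findInterval(minute, edges, rightmost.closed = TRUE)
  idx[minute < edges[1] | minute > edges[length(edges)]] <- NA_integer_
  labels[idx]
}

#' Annotate events with anatomical direction, depth, sector and window
#'
#' For each event the revised start position of the center cell is placed
#' in the anatomical coordinate system: the displacement component along
#' the outward EVL normal classifies the direction (up/down/lateral), the
#' signed inward distance in units of the reference cell diameter gives
#' the depth level, the angle to the animal-vegetal axis the sector, and
#' the start time the analysis window.
#'
#' @param events data.frame from \code{\link{computeKinematics}}.
#' @param tracks a \linkS4class{CellTracks} object.
#' @param surface an \linkS4class{EVLSurface}.
#' @param params an \code{\link{anatomyParams}} list.
#' @return The events data.frame with added columns \code{direction,
#'   depth_diam, sector, time_window}.
#' @export
annotateEvents <- function(events, tracks, surface,
                           params = anatomyParams()) {
  events$direction <- character(nrow(events))
  events$depth_diam <- NA_real_
  events$sector <- character(nrow(events))
  events$time_window <- character(nrow(events))
  if (!nrow(events)) return(events)
  pa <- .positionArray(tracks)
  dt <- frameInterval(tracks)
  for (r in seq_len(nrow(events))) {
    f <- events$frame_start_rev[r]
    rk <- match(events$center[r], pa$ids)
    p0 <- c(pa$X[rk, f + 1L], pa$Y[rk, f + 1L], pa$Z[rk, f + 1L])
    nrm <- surfaceNormal(surface, f, matrix(p0, 1))[1, ]
    disp <- c(events$dx[r], events$dy[r], events$dz[r])
    events$direction[r] <- classifyDirection(disp, nrm,
                                             params$lateralHalfWidth)
    events$depth_diam[r] <- depthOf(matrix(p0, 1), surface, f,
                                    params$cellDiameter)
    events$sector[r] <- assignSector(matrix(p0, 1), surface, f,
                                     params$sectorHalfAngle)
    events$time_window[r] <- assignTimeWindow(f, dt,
                                              params$timeWindowEdges,
                                              params$timeWindowLabels)
  }
  events
}
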