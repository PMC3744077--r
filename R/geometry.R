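#' Capped 3D Voronoi tessellation of one frame
#'
#' Builds the per-frame cell neighborhood from nuclei positions: each
#' virtual cell is the intersection of the nucleus's Voronoi region with a
#' sphere of \code{capRadius} around the nucleus, which bounds boundary
#' cells to a realistic size. Two cells are neighbors when their capped
#' regions share a face of positive area; that face area is the cell-cell
#' contact area.
#'
#' Faces are computed exactly as convex polygons on the seed-pair bisector
#' planes; the circular face boundary contributed by the cap sphere is
#' approximated by an inscribed 128-gon (relative area error below 1e-3).
#' Cell volumes are computed by the divergence theorem, with the spherical
#' patch area estimated on a 1500-point Fibonacci direction lattice.
#'
#' @param positions numeric matrix (n x 3) of nuclei positions in
#'   micrometres.
#' @param capRadius cap-sphere radius in micrometres (default 20).
#' @param ids optional integer track ids for the rows of \code{positions}.
#' @param frame 0-based frame index stored in the result.
#' @param volumes compute capped cell volumes (default TRUE).
#' @param nCircle number of polygon vertices approximating circular face
#'   boundaries.
#' @return A \linkS4class{NeighborhoodGraph}.
#' @examples
#' g <- computeVoronoi(rbind(c(0, 0, 0), c(10, 0, 0)))
#' contactArea(g, 1, 2)
#' @export
computeVoronoi <- function(positions, capRadius = 20, ids = NULL,
                           frame = 0L, volumes = TRUE, nCircle = 128L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  if (nrow(positions) < 1L) stop("at least one seed is required")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (is.null(ids)) ids <- seq_len(nrow(positions))
  ids <- as.integer(ids)
  res <- .voronoi_capped_cpp(positions, capRadius, as.integer(nCircle),
                             1500L, volumes)
  edges <- data.frame(a = ids[res$i], b = ids[res$j], area = res$area)
  swap <- edges$a > edges$b
  if (any(swap)) {
    tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  }
  new("NeighborhoodGraph", frame = as.integer(frame), ids = ids,
      edges = edges[order(edges$a, edges$b), , drop = FALSE],
      volumes = if (volumes) res$volume else numeric(0),
      capRadius = capRadius)
}

#' Cell-cell contact area
#'
#' @param graph a \linkS4class{NeighborhoodGraph}.
#' @param i,j track ids of two cells in the graph.
#' @return Contact area in square micrometres; 0 for non-adjacent cells.
#' @name contactArea
#' @export
setMethod("contactArea", "NeighborhoodGraph", function(graph, i, j) {
  if (!(i %in% graph@ids)) stop("unknown node id: ", i)
  if (!(j %in% graph@ids)) stop("unknown node id: ", j)
  if (i == j) return(0)
  a <- min(i, j); b <- max(i, j)
  hit <- graph@edges$a == a & graph@edges$b == b
  if (any(hit)) graph@edges$area[hit][1] else 0
})

#' Capped Voronoi cell volume
#'
#' @param graph a \linkS4class{NeighborhoodGraph} built with
#'   \code{volumes = TRUE}.
#' @param i track id of a cell in the graph.
#' @return Cell volume in cubic micrometres.
#' @name cellVolume
#' @export
setMethod("cellVolume", "NeighborhoodGraph", function(graph, i) {
  if (!length(graph@volumes)) stop("graph was built without volumes")
  k <- match(i, graph@ids)
  if (is.na(k)) stop("unknown node id: ", i)
  graph@volumes[k]
})

#' Interior angles of a cell triple
#'
#' The enclosing angles of the triangle formed by three nuclei positions,
#' in degrees, at vertices i, j and k respectively. In the three-stage
#' intercalation model the triple starts near an equiangular configuration
#' and ends collinear with the center cell k between i and j
#' (w_k = 180 degrees).
#'
#' @param pi_,pj_,pk_ numeric 3-vectors, positions in micrometres.
#' @return Named numeric vector \code{c(w_i, w_j, w_k)}; the angles sum to
#'   180 degrees.
#' @examples
#' pairwiseAngles(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
#' @export
pairwiseAngles <- function(pi_, pj_, pk_) {
  P <- rbind(pi_, pj_, pk_)
  if (!all(is.finite(P))) stop("positions must be finite")
  dij <- sqrt(sum((pi_ - pj_)^2))
  djk <- sqrt(sum((pj_ - pk_)^2))
  dki <- sqrt(sum((pk_ - pi_)^2))
  if (min(dij, djk, dki) < .Machine$double.eps)
    stop("coincident points in triple")
  ang <- function(a, b, c) {  # angle opposite side a, degrees
    acos(.clamp((b^2 + c^2 - a^2) / (2 * b * c), -1, 1)) * 180 / pi
  }
  c(w_i = ang(djk, dij, dki), w_j = ang(dki, dij, djk),
    w_k = ang(dij, djk, dki))
}

#' Reference cell diameter from nearest-neighbor statistics
#'
#' Median, over all (cell, frame) observations, of the distance from each
#' nucleus to its nearest neighbor in the same frame. Used as the
#' reference cell diameter d for discretising depths into cell-diameter
#' levels and for the lateral classification band.
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @return Median nearest-neighbor distance in micrometres.
#' @export
nearestNeighborDiameter <- function(tracks) {
  stopifnot(is(tracks, "CellTracks"))
  d <- tracks@data
  nn <- unlist(lapply(split(seq_len(nrow(d)), d$frame), function(rows) {
    if (length(rows) < 2L) return(numeric(0))
    P <- as.matrix(d[rows, c("x_um", "y_um", "z_um")])
    D <- as.matrix(stats::dist(P))
    diag(D) <- Inf
    apply(D, 1L, min)
  }), use.names = FALSE)
  if (!length(nn)) stop("no frame contains at least two cells")
  median(nn)
}

#' Per-frame neighborhood graphs for a trajectory table
#'
#' Tessellates every frame of a trajectory table, after linear
#' interpolation of within-track gaps (at most \code{maxGap} frames, the
#' tracking gap tolerance), so that feature series of cell triples are
#' continuous across short mitosis-induced tracking gaps.
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @param capRadius cap-sphere radius in micrometres (default 20).
#' @param volumes compute per-cell volumes (default FALSE; they are not
#'   needed for event detection).
#' @param nCircle circular-boundary polygon resolution.
#' @return List of \linkS4class{NeighborhoodGraph}, one per frame (frames
#'   with fewer than 2 cells yield empty graphs).
#' @export
buildNeighborhoodGraphs <- function(tracks, capRadius = 20, volumes = FALSE,
                                    nCircle = 128L) {
  pa <- .positionArray(tracks)
  lapply(seq_len(pa$nFrames), function(f) {
    present <- which(is.finite(pa$X[, f]))
    if (length(present) < 2L) {
      return(new("NeighborhoodGraph", frame = f - 1L,
                 ids = pa$ids[present],
                 edges = data.frame(a = integer(0), b = integer(0),
                                    area = numeric(0)),
                 volumes = numeric(0), capRadius = capRadius))
    }
    P <- cbind(pa$X[present, f], pa$Y[present, f], pa$Z[present, f])
    computeVoronoi(P, capRadius = capRadius, ids = pa$ids[present],
                   frame = f - 1L, volumes = volumes, nCircle = nCircle)
  })
}
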