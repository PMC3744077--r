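#' @import methods
NULL

#' Tracked nuclei positions over time
#'
#' Container for 3D nucleus trajectories: one row per (track, frame) with
#' positions in micrometres and an optional flag marking nuclei of the
#' enveloping layer (EVL), the outermost epithelial monolayer used as the
#' anatomical reference surface. Tracks may contain internal gaps of at most
#' \code{maxGap} frames (nuclear labels are lost during mitosis, so tracks
#' cover the interval between two divisions); gaps are linearly interpolated
#' before any geometric computation.
#'
#' @slot data data.frame with columns \code{track_id} (integer),
#'   \code{frame} (0-based integer), \code{x_um}, \code{y_um}, \code{z_um}
#'   (numeric, micrometres) and \code{is_evl} (logical).
#' @slot frameInterval numeric, minutes between consecutive frames.
#' @slot maxGap integer, the largest tolerated within-track frame gap.
#'
#' @export
setClass("CellTracks",
  representation(data = "data.frame", frameInterval = "numeric",
                 maxGap = "integer"),
  prototype(frameInterval = 1.05, maxGap = 2L))

setValidity("CellTracks", function(object) {
  d <- object@data
  need <- c("track_id", "frame", "x_um", "y_um", "z_um", "is_evl")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  if (nrow(d) == 0L) return(TRUE)
  if (anyDuplicated(d[, c("track_id", "frame")]))
    return("(track_id, frame) pairs must be unique")
  if (!all(is.finite(as.matrix(d[, c("x_um", "y_um", "z_um")]))))
    return("positions must be finite")
  if (any(d$frame < 0)) return("frames must be >= 0")
  gaps <- vapply(split(d$frame, d$track_id),
                 function(f) if (length(f) < 2L) 0L else max(diff(sort(f))) - 1L,
                 integer(1))
  if (any(gaps > object@maxGap))
    return(sprintf("track gap exceeds maxGap = %d", object@maxGap))
  TRUE
})

#' Construct a CellTracks object
#'
#' @param data data.frame with columns \code{track_id}, \code{frame},
#'   \code{x_um}, \code{y_um}, \code{z_um} and optionally \code{is_evl}
#'   (defaults to \code{FALSE}).
#' @param frameInterval minutes per frame (default 1.05).
#' @param maxGap largest tolerated within-track frame gap (default 2).
#' @return A \linkS4class{CellTracks} object.
#' @examples
#' d <- data.frame(track_id = 1L, frame = 0:2, x_um = 0, y_um = 0,
#'                 z_um = c(0, 1, 2))
#' CellTracks(d)
#' @export
CellTracks <- function(data, frameInterval = 1.05, maxGap = 2L) {
  data <- as.data.frame(data)
  if (is.null(data$is_evl)) data$is_evl <- FALSE
  data$track_id <- as.integer(data$track_id)
  data$frame <- as.integer(data$frame)
  data$is_evl <- as.logical(data$is_evl)
  data <- data[order(data$track_id, data$frame),
               c("track_id", "frame", "x_um", "y_um", "z_um", "is_evl")]
  rownames(data) <- NULL
  new("CellTracks", data = data, frameInterval = as.numeric(frameInterval),
      maxGap = as.integer(maxGap))
}

setMethod("show", "CellTracks", function(object) {
  d <- object@data
  cat(sprintf("CellTracks: %d tracks, %d frames (%.2f min interval), %d rows, %d EVL nuclei\n",
              length(unique(d$track_id)),
              if (nrow(d)) max(d$frame) + 1L else 0L,
              object@frameInterval, nrow(d),
              length(unique(d$track_id[d$is_evl]))))
})

#' Per-frame Voronoi neighborhood graph
#'
#' Adjacency of cells in one frame derived from the capped 3D Voronoi
#' tessellation of nuclei seeds: an edge exists where two capped Voronoi
#' cells share a face of positive area (the cell-cell contact area in
#' square micrometres).
#'
#' @slot frame integer, 0-based frame index.
#' @slot ids integer vector of track ids present in this frame.
#' @slot edges data.frame with columns \code{a}, \code{b} (track ids,
#'   \code{a < b}) and \code{area} (square micrometres).
#' @slot volumes numeric vector of capped cell volumes (cubic micrometres),
#'   parallel to \code{ids}; may be empty when not computed.
#' @slot capRadius numeric, cap-sphere radius in micrometres.
#'
#' @export
setClass("NeighborhoodGraph",
  representation(frame = "integer", ids = "integer", edges = "data.frame",
                 volumes = "numeric", capRadius = "numeric"))

setValidity("NeighborhoodGraph", function(object) {
  e <- object@edges
  if (!all(c("a", "b", "area") %in% names(e))) return("edges need a, b, area")
  if (nrow(e)) {
    if (any(e$a == e$b)) return("self edges are not allowed")
    if (any(e$area <= 0)) return("contact areas must be positive")
    if (!all(c(e$a, e$b) %in% object@ids)) return("edge endpoint not in ids")
  }
  if (length(object@volumes) && length(object@volumes) != length(object@ids))
    return("volumes must be parallel to ids")
  TRUE
})

setMethod("show", "NeighborhoodGraph", function(object) {
  cat(sprintf("NeighborhoodGraph: frame %d, %d cells, %d contacts (cap %.1f um)\n",
              object@frame, length(object@ids), nrow(object@edges),
              object@capRadius))
})

#' Three-stage intercalation template
#'
#' Idealised time course of the six features of a cell triple (i, j, k)
#' undergoing an intercalation in which the center cell k inserts between
#' its neighbors i and j: the enclosing angles w_i, w_j, w_k (degrees) and
#' the mutual contact areas a_ij, a_jk, a_ki (square micrometres). The
#' triple starts in a triangular configuration (stage T1) and ends in a
#' linear one (stage T3, w_k = 180 degrees). All features transition
#' linearly except a_ij, which decays linearly to zero at stage T2 (cells i
#' and j lose contact) and stays zero until T3.
#'
#' @slot startValues named numeric of length 6
#'   (\code{w_i, w_j, w_k, a_ij, a_jk, a_ki}) at stage T1.
#' @slot endValues same layout at stage T3; \code{a_ij} must be 0 and
#'   \code{w_k} must be 180.
#' @slot t2Fraction relative position of stage T2 within the window, in
#'   (0, 1].
#'
#' @export
setClass("IntercalationTemplate",
  representation(startValues = "numeric", endValues = "numeric",
                 t2Fraction = "numeric"))

.featNames <- c("w_i", "w_j", "w_k", "a_ij", "a_jk", "a_ki")

setValidity("IntercalationTemplate", function(object) {
  s <- object@startValues; e <- object@endValues
  if (!identical(names(s), .featNames) || !identical(names(e), .featNames))
    return("start/end values must be named w_i, w_j, w_k, a_ij, a_jk, a_ki")
  if (abs(sum(s[1:3]) - 180) > 1e-6) return("start angles must sum to 180")
  if (abs(e[["w_k"]] - 180) > 1e-9) return("end configuration must have w_k = 180")
  if (abs(e[["a_ij"]]) > 1e-12) return("a_ij must end at 0")
  if (any(s[4:6] < 0) || any(e[4:6] < 0)) return("areas must be >= 0")
  if (s[["w_k"]] >= e[["w_k"]]) return("w_k must increase from start to end")
  t2 <- object@t2Fraction
  if (length(t2) != 1L || t2 <= 0 || t2 > 1) return("t2Fraction must be in (0, 1]")
  TRUE
})

setMethod("show", "IntercalationTemplate", function(object) {
  cat("IntercalationTemplate (triangular T1 -> linear T3)\n")
  cat("  start:", paste(sprintf("%s=%.4g", .featNames, object@startValues),
                        collapse = " "), "\n")
  cat("  end:  ", paste(sprintf("%s=%.4g", .featNames, object@endValues),
                        collapse = " "), "\n")
  cat(sprintf("  contact loss (T2) at relative time %.2f\n", object@t2Fraction))
})

#' Smooth anatomical reference surface fitted to EVL nuclei
#'
#' Per-frame near-spherical surface fitted to the enveloping-layer nuclei:
#' a least-squares sphere plus a low-order spherical-harmonics radial
#' correction of the nuclei radii about the fitted center. The surface
#' provides a signed depth (positive inward, toward the deep cell layer),
#' outward normals and the animal-vegetal axis (mean outward direction of
#' the EVL cap).
#'
#' @slot frames integer vector of fitted 0-based frame indices.
#' @slot center matrix (frames x 3) of fitted sphere centers, micrometres.
#' @slot radius numeric vector of fitted sphere radii, micrometres.
#' @slot coef matrix (frames x (lmax+1)^2) of radial-correction
#'   coefficients.
#' @slot lmax integer, spherical-harmonics degree of the radial correction.
#' @slot axis matrix (frames x 3) of unit animal-vegetal axis vectors
#'   (pointing to the animal pole).
#' @slot residualRMS numeric vector of per-frame RMS radial residuals of
#'   the EVL nuclei, micrometres.
#'
#' @export
setClass("EVLSurface",
  representation(frames = "integer", center = "matrix", radius = "numeric",
                 coef = "matrix", lmax = "integer", axis = "matrix",
                 residualRMS = "numeric"))

setValidity("EVLSurface", function(object) {
  n <- length(object@frames)
  if (nrow(object@center) != n || length(object@radius) != n ||
      nrow(object@coef) != n || nrow(object@axis) != n ||
      length(object@residualRMS) != n)
    return("per-frame slots must be parallel to frames")
  if (any(object@radius <= 0)) return("radii must be positive")
  nrm <- sqrt(rowSums(object@axis^2))
  if (any(abs(nrm - 1) > 1e-6)) return("axis vectors must be unit length")
  TRUE
})

setMethod("show", "EVLSurface", function(object) {
  cat(sprintf("EVLSurface: %d frames, mean radius %.1f um, SH correction l <= %d, mean residual RMS %.2f um\n",
              length(object@frames), mean(object@radius), object@lmax,
              mean(object@residualRMS)))
})

#' Aggregated intercalation analysis report
#'
#' Result of the full pipeline: annotated events, summary statistics
#' (counts, ratios, Poisson confidence intervals, depth profiles,
#' intercalation history, sector analyses) and the spherical-harmonics
#' directionality coefficients.
#'
#' @slot events data.frame of detected events with kinematic, verification
#'   and anatomical annotation columns.
#' @slot summary list of summary tables (see \code{\link{countSummary}},
#'   \code{\link{depthProfile}}, \code{\link{historyTree}},
#'   \code{\link{sectorExitRatio}}).
#' @slot coefficients data.frame (l, m, c) of spherical-harmonics
#'   coefficients of the verified-event direction distribution.
#' @slot params list of the parameter objects used.
#'
#' @export
setClass("IntercalationReport",
  representation(events = "data.frame", summary = "list",
                 coefficients = "data.frame", params = "list"))

setMethod("show", "IntercalationReport", function(object) {
  ev <- object@events
  nv <- if (nrow(ev) && "verified" %in% names(ev)) sum(ev$verified) else 0L
  cat(sprintf("IntercalationReport: %d candidate events, %d verified\n",
              nrow(ev), nv))
  cs <- object@summary$counts
  if (!is.null(cs)) {
    cat("  verified counts:",
        paste(sprintf("%s=%d", names(cs), cs), collapse = " "), "\n")
  }
  r <- object@summary$ratios
  if (!is.null(r))
    cat(sprintf("  up:down = %.3g, lateral:(up+down) = %.3g\n",
                r[["up_down"]], r[["lateral_radial"]]))
  c20 <- object@summary$c20
  if (!is.null(c20)) cat(sprintf("  polarity c20 = %.4f\n", c20))
})
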