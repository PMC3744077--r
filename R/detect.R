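#' Construct a three-stage intercalation template
#'
#' The ideal feature time course of an intercalation: published analyses
#' define the start and end values by inspecting clear events in the data,
#' so the defaults here are explicit calibration stand-ins, not measured
#' constants. Angles start near the equiangular configuration (60, 60, 60)
#' and end linear (0, 0, 180); the contact between the separating neighbor
#' pair (a_ij) starts at a typical contact area -- by default the dataset
#' median -- and reaches zero at the relative time \code{t2Fraction}; the
#' two contacts with the center cell stay at their start value.
#'
#' @param aStart ideal start contact area a_ij in square micrometres
#'   (typically the dataset median contact area).
#' @param startAngles,endAngles numeric length-3, degrees (w_i, w_j, w_k).
#' @param aSideStart,aSideEnd ideal contact areas a_jk = a_ki at start and
#'   end (default: constant at \code{aStart}).
#' @param t2Fraction relative time at which cells i and j lose contact.
#' @return An \linkS4class{IntercalationTemplate}.
#' @examples
#' tpl <- intercalationTemplate(aStart = 150)
#' templateValues(tpl, c(0, 0.5, 1))
#' @export
intercalationTemplate <- function(aStart, startAngles = c(60, 60, 60),
                                  endAngles = c(0, 0, 180),
                                  aSideStart = aStart, aSideEnd = aSideStart,
                                  t2Fraction = 0.5) {
  s <- c(startAngles, aStart, aSideStart, aSideStart)
  e <- c(endAngles, 0, aSideEnd, aSideEnd)
  names(s) <- .featNames; names(e) <- .featNames
  new("IntercalationTemplate", startValues = s, endValues = e,
      t2Fraction = t2Fraction)
}

#' Evaluate the template at relative times
#'
#' Linear interpolation between the start (T1) and end (T3) values for all
#' features except a_ij, which decays linearly to zero at the relative time
#' T2 (= \code{t2Fraction}) and is exactly zero from T2 to T3.
#'
#' @param template an \linkS4class{IntercalationTemplate}.
#' @param u relative time(s) in [0, 1].
#' @return Matrix (length(u) x 6) of feature values, columns
#'   \code{w_i, w_j, w_k, a_ij, a_jk, a_ki}.
#' @name templateValues
#' @export
setMethod("templateValues", "IntercalationTemplate", function(template, u) {
  u <- as.numeric(u)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("relative time u must lie in [0, 1]")
  s <- template@startValues; e <- template@endValues
  t2 <- template@t2Fraction
  out <- outer(1 - u, s) + outer(u, e)
  aij <- ifelse(u < t2, s[["a_ij"]] * (1 - u / t2), 0)
  out[, 4L] <- aij
  colnames(out) <- .featNames
  out
})

#' Detection parameter set
#'
#' @param scoreThreshold minimum event score s = exp(-d); candidates below
#'   it are discarded (default 0.85).
#' @param minDuration,maxDuration admissible window lengths in frames
#'   (default 4 and 20, about 4-21 minutes at a 1.05-min frame interval).
#' @param wMse per-feature weights of the fit mean squared errors, order
#'   \code{w_i, w_j, w_k, a_ij, a_jk, a_ki}. The defaults are calibrated
#'   on clear synthetic events so that template-following triples score
#'   well above the reliability threshold and static triples well below
#'   it: angle fits and the a_ij decay carry the discrimination, while
#'   the side contacts a_jk, a_ki (whose magnitude varies with local cell
#'   density) are down-weighted.
#' @param wPar per-feature weights of the fitted-endpoint deviations from
#'   the ideal endpoints (same order and calibration rationale).
#' @param overlapFraction windows of the same center cell overlapping more
#'   than this fraction of the shorter window are merged (default 0.5).
#' @param capRadius Voronoi cap radius in micrometres (default 20).
#' @return Named list of detection parameters.
#' @export
detectionParams <- function(scoreThreshold = 0.85, minDuration = 4L,
                            maxDuration = 20L,
                            wMse = c(1, 1, 1, 0.15, 0.02, 0.02),
                            wPar = c(0.6, 0.6, 0.6, 0.03, 0.005, 0.005),
                            overlapFraction = 0.5, capRadius = 20) {
  stopifnot(scoreThreshold > 0, scoreThreshold <= 1,
            minDuration >= 3, maxDuration >= minDuration,
            length(wMse) == 6L, length(wPar) == 6L,
            all(wMse >= 0), all(wPar >= 0), all(wMse + wPar > 0))
  list(scoreThreshold = scoreThreshold, minDuration = as.integer(minDuration),
       maxDuration = as.integer(maxDuration), wMse = wMse, wPar = wPar,
       overlapFraction = overlapFraction, capRadius = capRadius)
}

#' Feature series of one cell triple
#'
#' Per-frame six-feature vectors of a triple (i, j, k): the enclosing
#' angles from the nuclei positions and the three mutual contact areas
#' from the per-frame Voronoi graphs. Cells that are tracked but not in
#' contact contribute a zero area.
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @param graphs per-frame graphs from \code{\link{buildNeighborhoodGraphs}}.
#' @param i,j neighbor track ids; \code{k} center track id.
#' @param k center track id.
#' @param window integer length-2, 0-based first and last frame.
#' @return data.frame with columns \code{frame, w_i, w_j, w_k, a_ij, a_jk,
#'   a_ki}.
#' @export
featureSeries <- function(tracks, graphs, i, j, k, window) {
  pa <- .positionArray(tracks)
  frames <- seq(window[1], window[2])
  ri <- match(i, pa$ids); rj <- match(j, pa$ids); rk <- match(k, pa$ids)
  if (anyNA(c(ri, rj, rk))) stop("unknown track id")
  cols <- frames + 1L
  P <- function(r) cbind(pa$X[r, cols], pa$Y[r, cols], pa$Z[r, cols])
  Pi <- P(ri); Pj <- P(rj); Pk <- P(rk)
  if (anyNA(Pi) || anyNA(Pj) || anyNA(Pk))
    stop("track absent (beyond the interpolated gap) within the window")
  ang <- t(vapply(seq_along(frames), function(t)
    pairwiseAngles(Pi[t, ], Pj[t, ], Pk[t, ]), numeric(3)))
  area <- function(a, b) vapply(seq_along(frames), function(t)
    contactArea(graphs[[frames[t] + 1L]], a, b), numeric(1))
  data.frame(frame = frames, w_i = ang[, 1], w_j = ang[, 2], w_k = ang[, 3],
             a_ij = area(i, j), a_jk = area(j, k), a_ki = area(k, i))
}

# least-squares endpoint fit of one feature over u in [0, 1]
.fitFeature <- function(y, u, decay = FALSE, t2 = 0.5) {
  n <- length(y)
  if (decay) {
    b <- ifelse(u < t2, 1 - u / t2, 0)
    q <- sum(y * b) / sum(b * b)
    list(p0 = q, p1 = 0, mse = mean((y - q * b)^2))
  } else {
    fit <- stats::lm.fit(cbind(1, u), y)
    p <- fit$coefficients
    list(p0 = p[1], p1 = p[1] + p[2], mse = mean(fit$residuals^2))
  }
}

#' Combined fit error of a feature series against the template
#'
#' Features are normalised (angles by 180 degrees, areas by
#' \code{areaScale}) so the per-feature weights are comparable; per feature
#' the free template endpoints are fitted by least squares and the error is
#' the weighted sum of the fit mean squared errors plus the weighted mean
#' absolute deviation of the fitted endpoints from the ideal endpoints.
#' The error is zero exactly when the series follows the template at the
#' ideal endpoints.
#'
#' @param series data.frame from \code{\link{featureSeries}} (at least 3
#'   frames).
#' @param template an \linkS4class{IntercalationTemplate}.
#' @param wMse,wPar per-feature weights (see \code{\link{detectionParams}}).
#' @param areaScale area normalisation in square micrometres (default: the
#'   template's start contact area a_ij).
#' @return Non-negative scalar error d.
#' @export
fitError <- function(series, template, wMse = detectionParams()$wMse,
                     wPar = detectionParams()$wPar, areaScale = NULL) {
  if (nrow(series) < 3L) stop("series must span at least 3 frames")
  if (any(wMse < 0) || any(wPar < 0) || all(c(wMse, wPar) == 0))
    stop("weights must be non-negative and not all zero")
  if (is.null(areaScale)) areaScale <- template@startValues[["a_ij"]]
  u <- seq(0, 1, length.out = nrow(series))
  scale <- c(180, 180, 180, rep(areaScale, 3))
  iS <- template@startValues / scale
  iE <- template@endValues / scale
  d <- 0
  for (f in seq_len(6L)) {
    y <- series[[.featNames[f]]] / scale[f]
    fit <- .fitFeature(y, u, decay = (f == 4L), t2 = template@t2Fraction)
    dev <- 0.5 * (abs(fit$p0 - iS[f]) + abs(fit$p1 - iE[f]))
    d <- d + wMse[f] * fit$mse + wPar[f] * dev
  }
  unname(d)
}

#' Convert a fit error to a reliability score
#'
#' @param d non-negative fit error.
#' @return Score s = exp(-d) in (0, 1].
#' @export
eventScore <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("fit error must be >= 0")
  exp(-d)
}

#' Detect candidate intercalation events
#'
#' Fits the three-stage template to every candidate triple and window: for
#' each center cell k and each pair of cells (i, j) that are Voronoi
#' neighbors of k and of each other at the window start, the template is
#' fitted over all admissible windows. Per start frame the best window is
#' kept, local maxima of the score over start time become candidate
#' events, overlapping candidates are joined (same triple: intersecting
#' windows; same center: windows overlapping more than
#' \code{overlapFraction} of the shorter), and candidates scoring below
#' \code{scoreThreshold} are discarded.
#'
#' @param tracks a \linkS4class{CellTracks} object.
#' @param graphs optional precomputed per-frame graphs.
#' @param template optional \linkS4class{IntercalationTemplate}; by default
#'   built with the dataset median contact area as start area.
#' @param params a \code{\link{detectionParams}} list.
#' @return data.frame with columns \code{event_id, center, neighbor_a,
#'   neighbor_b, frame_start, frame_end, d_err, score}.
#' @export
detectEvents <- function(tracks, graphs = NULL, template = NULL,
                         params = detectionParams()) {
  stopifnot(is(tracks, "CellTracks"))
  empty <- data.frame(event_id = integer(0), center = integer(0),
                      neighbor_a = integer(0), neighbor_b = integer(0),
                      frame_start = integer(0), frame_end = integer(0),
                      d_err = numeric(0), score = numeric(0))
  if (nrow(tracks@data) == 0L) return(empty)
  pa <- .positionArray(tracks)
  if (pa$nFrames < params$minDuration) return(empty)
  if (is.null(graphs))
    graphs <- buildNeighborhoodGraphs(tracks, capRadius = params$capRadius)
  E <- data.table::rbindlist(lapply(graphs, function(g) {
    if (!nrow(g@edges)) return(NULL)
    data.table::data.table(frame = g@frame, a = g@edges$a, b = g@edges$b,
                           area = g@edges$area)
  }))
  if (is.null(E) || !nrow(E)) return(empty)
  medA <- median(E$area)
  if (is.null(template)) template <- intercalationTemplate(aStart = medA)
  areaScale <- template@startValues[["a_ij"]]
  scale <- c(180, 180, 180, rep(areaScale, 3))
  idealS <- template@startValues / scale
  idealE <- template@endValues / scale

  # -- enumerate triangles (a < b < c all mutually adjacent) per frame
  E2 <- E[, list(frame, a, b)]
  data.table::setkey(E2, frame, a, b)
  tri <- E2[E2, on = c("frame", "a"), allow.cartesian = TRUE]
  data.table::setnames(tri, c("frame", "a", "c", "b"))
  tri <- tri[tri$b < tri$c, ]
  hit <- E2[tri, on = c(frame = "frame", a = "b", b = "c"), which = TRUE]
  tri <- tri[!is.na(hit), list(frame, a, b, c)]
  if (!nrow(tri)) return(empty)

  # -- centered triples: every triangle vertex can be the center
  trip <- data.table::rbindlist(list(
    tri[, list(frame, center = c, p1 = a, p2 = b)],
    tri[, list(frame, center = b, p1 = a, p2 = c)],
    tri[, list(frame, center = a, p1 = b, p2 = c)]))
  key <- paste(trip$center, trip$p1, trip$p2)
  uniq <- !duplicated(key)
  triples <- trip[uniq, list(center, p1, p2)]
  tripleOf <- match(key, key[uniq])
  nTrip <- nrow(triples)
  nF <- pa$nFrames

  # -- feature series for all triples at once
  rC <- match(triples$center, pa$ids)
  r1 <- match(triples$p1, pa$ids)
  r2 <- match(triples$p2, pa$ids)
  G <- data.table::data.table(
    triple = rep(seq_len(nTrip), each = nF),
    frame = rep.int(0:(nF - 1L), nTrip))
  colIdx <- G$frame + 1L
  pos <- function(r) cbind(pa$X[cbind(r, colIdx)], pa$Y[cbind(r, colIdx)],
                           pa$Z[cbind(r, colIdx)])
  Pk <- pos(rep(rC, each = nF))
  Pi <- pos(rep(r1, each = nF))
  Pj <- pos(rep(r2, each = nF))
  d2 <- function(A, B) sqrt(rowSums((A - B)^2))
  dij <- d2(Pi, Pj); djk <- d2(Pj, Pk); dki <- d2(Pk, Pi)
  angAt <- function(opp, s1, s2)
    acos(.clamp((s1^2 + s2^2 - opp^2) / (2 * s1 * s2), -1, 1)) * 180 / pi
  wi <- angAt(djk, dij, dki); wj <- angAt(dki, dij, djk)
  wk <- angAt(dij, djk, dki)
  lookup <- function(u, v) {
    q <- data.table::data.table(frame = G$frame, a = pmin(u, v),
                                b = pmax(u, v))
    ar <- E[q, on = c("frame", "a", "b")]$area
    ar[is.na(ar)] <- 0
    ar
  }
  idK <- rep(triples$center, each = nF)
  id1 <- rep(triples$p1, each = nF)
  id2 <- rep(triples$p2, each = nF)
  aij <- lookup(id1, id2); ajk <- lookup(id2, idK); aki <- lookup(idK, id1)
  absent <- !is.finite(dij) | !is.finite(djk) | !is.finite(dki)
  aij[absent] <- NA_real_; ajk[absent] <- NA_real_; aki[absent] <- NA_real_

  Fall <- cbind(wi / 180, wj / 180, wk / 180,
                aij / areaScale, ajk / areaScale, aki / areaScale)

  validAll <- logical(nTrip * nF)
  validAll[(trip$frame + 1L) + (tripleOf - 1L) * nF] <- TRUE

  # -- score windows per triple, pick local score maxima over start time
  cand <- .detect_candidates_cpp(Fall, validAll, nTrip, nF,
                                 params$minDuration, params$maxDuration,
                                 template@t2Fraction, idealS, idealE,
                                 params$wMse, params$wPar)
  if (!nrow(cand)) return(empty)
  ev <- data.frame(triple = as.integer(cand[, 1L]),
                   frame_start = as.integer(cand[, 2L]),
                   frame_end = as.integer(cand[, 3L]),
                   d_err = cand[, 4L])
  ev$center <- triples$center[ev$triple]
  ev$neighbor_a <- triples$p1[ev$triple]
  ev$neighbor_b <- triples$p2[ev$triple]
  ev$score <- exp(-ev$d_err)

  # -- join overlapping candidates into the max-score window (greedy by
  #    score; ties: earlier start, then lexicographic triple ids): any
  #    overlap joins windows of the same triple; overlap beyond
  #    overlapFraction of the shorter window joins candidates sharing any
  #    of their three cells (a cell takes part in only one insertion at a
  #    time; echoes of one insertion seen from nearby triples collapse
  #    onto the best-fitting description)
  # (thresholding before joining is equivalent: suppression only ever
  # flows from higher-scoring to lower-scoring candidates)
  ev <- ev[ev$score >= params$scoreThreshold, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  ev <- ev[order(-ev$score, ev$frame_start, ev$center, ev$neighbor_a,
                 ev$neighbor_b), ]
  cells <- cbind(ev$center, ev$neighbor_a, ev$neighbor_b)
  keepRow <- logical(nrow(ev))
  for (r in seq_len(nrow(ev))) {
    kept <- which(keepRow)
    if (length(kept)) {
      o <- pmin(ev$frame_end[kept], ev$frame_end[r]) -
           pmax(ev$frame_start[kept], ev$frame_start[r]) + 1L
      len <- pmin(ev$frame_end[kept] - ev$frame_start[kept],
                  ev$frame_end[r] - ev$frame_start[r]) + 1L
      sameTriple <- ev$triple[kept] == ev$triple[r]
      shared <- vapply(kept, function(q)
        sum(cells[r, ] %in% cells[q, ]), integer(1))
      if (any(sameTriple & o > 0L) ||
          any(shared >= 1L & o / len > params$overlapFraction)) next
    }
    keepRow[r] <- TRUE
  }
  ev <- ev[keepRow, ]
  if (!nrow(ev)) return(empty)
  ev <- ev[order(ev$frame_start, ev$center), ]
  data.frame(event_id = seq_len(nrow(ev)), center = ev$center,
             neighbor_a = ev$neighbor_a, neighbor_b = ev$neighbor_b,
             frame_start = ev$frame_start, frame_end = ev$frame_end,
             d_err = ev$d_err, score = ev$score, row.names = NULL)
}
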