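#' intercalR: radial intercalation analysis of 3D nuclei trajectories
#'
#' Detects, refines, verifies and classifies cell intercalation events from
#' 3D time-lapse trajectories of cell nuclei, and aggregates them into the
#' summary statistics used to study deep-cell behavior during zebrafish
#' epiboly: direction counts and ratios, depth profiles, intercalation
#' histories, sector and time-window analyses, speeds and
#' spherical-harmonics directionality distributions.
#'
#' @useDynLib intercalR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
#' @importFrom stats median prcomp rnorm pnorm qchisq approx sd cov runif
#' @importFrom utils combn read.csv write.csv
#' @name intercalR-package
#' @aliases intercalR
#' @keywords internal
"_PACKAGE"

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("zero-length vector cannot be normalized")
  v / n
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# rotation matrix carrying unit vector `axis` onto +z (Rodrigues)
.rotationToZ <- function(axis) {
  a <- .unit(axis)
  z <- c(0, 0, 1)
  v <- c(a[2] * z[3] - a[3] * z[2],
         a[3] * z[1] - a[1] * z[3],
         a[1] * z[2] - a[2] * z[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(a * z)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # flip about x for antipodal axis
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# positions of all tracks as frame-indexed matrices with internal gaps
# (<= maxGap frames) linearly interpolated; no extrapolation
.positionArray <- function(tracks) {
  stopifnot(is(tracks, "CellTracks"))
  d <- tracks@data
  ids <- sort(unique(d$track_id))
  nF <- max(d$frame) + 1L
  nT <- length(ids)
  X <- matrix(NA_real_, nT, nF); Y <- X; Z <- X
  row <- match(d$track_id, ids)
  idx <- cbind(row, d$frame + 1L)
  X[idx] <- d$x_um; Y[idx] <- d$y_um; Z[idx] <- d$z_um
  # interpolate internal gaps per track
  gapped <- which(vapply(seq_len(nT), function(r) {
    f <- which(!is.na(X[r, ]))
    length(f) >= 2L && any(diff(f) > 1L)
  }, logical(1)))
  for (r in gapped) {
    f <- which(!is.na(X[r, ]))
    full <- seq(min(f), max(f))
    X[r, full] <- approx(f, X[r, f], xout = full)$y
    Y[r, full] <- approx(f, Y[r, f], xout = full)$y
    Z[r, full] <- approx(f, Z[r, f], xout = full)$y
  }
  evl <- vapply(split(d$is_evl, d$track_id), any, logical(1))[as.character(ids)]
  list(ids = ids, nFrames = nF, X = X, Y = Y, Z = Z, isEVL = unname(evl))
}
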