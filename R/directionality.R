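# index layout of real spherical harmonics up to lmax: for each degree l,
# orders m = -l..l; (lmax+1)^2 basis functions in total
.shDegrees <- function(lmax) {
  l <- unlist(lapply(0:lmax, function(ll) rep(ll, 2 * ll + 1)))
  m <- unlist(lapply(0:lmax, function(ll) -ll:ll))
  list(l = l, m = m)
}

# real orthonormal spherical harmonics (Condon-Shortley phase, as in the
# MATLAB/pracma associated Legendre convention):
#   Y_l0            = N_l0 P_l0(cos theta)
#   Y_lm  (m > 0)   = sqrt(2) N_lm P_lm(cos theta) cos(m phi)
#   Y_l,-m (m > 0)  = sqrt(2) N_lm P_lm(cos theta) sin(m phi)
# with N_lm = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!); the basis is orthonormal
# on the unit sphere.
.realSH <- function(lmax, theta, phi) {
  n <- length(theta)
  x <- cos(theta)
  out <- matrix(0, n, (lmax + 1L)^2)
  colidx <- 0L
  for (l in 0:lmax) {
    P <- pracma::legendre(l, x)           # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1L)
    for (m in (-l):l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      colidx <- colidx + 1L
      out[, colidx] <-
        if (m == 0) N * P[1L, ]
        else if (m > 0) sqrt(2) * N * P[am + 1L, ] * cos(am * phi)
        else sqrt(2) * N * P[am + 1L, ] * sin(am * phi)
    }
  }
  out
}

#' Rotate vectors into the anatomical frame
#'
#' Applies the rotation carrying the animal-vegetal axis onto +z, so that
#' the polar angle of the spherical-harmonics expansion is measured from
#' the animal pole.
#'
#' @param vectors matrix (n x 3).
#' @param axis animal-vegetal axis (3-vector, toward the animal pole).
#' @return Rotated matrix (n x 3).
#' @export
toAnatomicalFrame <- function(vectors, axis) {
  vectors <- matrix(vectors, ncol = 3)
  vectors %*% t(.rotationToZ(axis))
}

#' Spherical-harmonics expansion of a direction distribution
#'
#' Displacement vectors are projected onto the unit sphere (magnitudes
#' discarded, or used as weights when \code{weights} is given) and the
#' empirical direction distribution is expanded in real orthonormal
#' spherical harmonics: c_lm is the (weighted) mean of Y_lm over the unit
#' directions. The polar angle is measured from +z; rotate vectors with
#' \code{\link{toAnatomicalFrame}} first so +z is the animal pole.
#'
#' @param vectors matrix (n x 3) of displacement vectors.
#' @param lmax maximum degree (default 10).
#' @param weights optional non-negative weights (normalised internally).
#' @return data.frame with columns \code{l, m, c}.
#' @examples
#' co <- shExpand(rbind(c(0, 0, 1), c(0, 0, -1)))
#' polarityC20(co)  # positive: signal at the poles
#' @export
shExpand <- function(vectors, lmax = 10L, weights = NULL) {
  vectors <- matrix(vectors, ncol = 3)
  if (!nrow(vectors)) stop("at least one direction is required")
  r <- sqrt(rowSums(vectors^2))
  if (any(r < .Machine$double.eps)) stop("zero-length vectors rejected")
  U <- vectors / r
  theta <- acos(.clamp(U[, 3], -1, 1))
  phi <- atan2(U[, 2], U[, 1])
  Y <- .realSH(lmax, theta, phi)
  if (is.null(weights)) {
    cc <- colMeans(Y)
  } else {
    stopifnot(length(weights) == nrow(vectors), all(weights >= 0))
    w <- weights / sum(weights)
    cc <- as.vector(t(Y) %*% w)
  }
  deg <- .shDegrees(lmax)
  data.frame(l = deg$l, m = deg$m, c = cc)
}

#' Polarity coefficient c_20
#'
#' The degree-2, order-0 expansion coefficient: positive when directions
#' concentrate at the poles of the animal-vegetal axis, negative when they
#' concentrate at the equator, and zero for a uniform distribution.
#'
#' @param coefficients data.frame from \code{\link{shExpand}}.
#' @return Scalar c_20.
#' @export
polarityC20 <- function(coefficients) {
  coefficients$c[coefficients$l == 2 & coefficients$m == 0]
}

#' Zonal (north-to-south) profile of a direction distribution
#'
#' Sum of the zonal terms c_l0 Y_l0 as a function of the polar angle: the
#' direction density averaged along the latitudes.
#'
#' @param coefficients data.frame from \code{\link{shExpand}}.
#' @param n number of polar-angle samples (default 181).
#' @return data.frame with columns \code{theta_deg} (0 = animal pole) and
#'   \code{value}.
#' @export
zonalProfile <- function(coefficients, n = 181L) {
  z <- coefficients[coefficients$m == 0, ]
  theta <- seq(0, pi, length.out = n)
  Y <- .realSH(max(z$l), theta, rep(0, n))
  deg <- .shDegrees(max(z$l))
  cols <- which(deg$m == 0)
  vals <- as.vector(Y[, cols, drop = FALSE] %*% z$c[match(deg$l[cols], z$l)])
  data.frame(theta_deg = theta * 180 / pi, value = vals)
}

#' 3D kernel density of displacement vectors
#'
#' Accumulates event displacement vectors (event start at the origin) into
#' a single 3D density with an isotropic Gaussian kernel on a regular
#' grid, plus the three axis-aligned central cross-sections used for
#' plotting.
#'
#' @param vectors matrix (n x 3) of displacement vectors in micrometres.
#' @param bandwidth Gaussian kernel standard deviation in micrometres
#'   (default 2).
#' @param gridSize voxels per axis (default 64).
#' @param extent half-width of the grid in micrometres (default 24).
#' @return List with \code{axes} (voxel center coordinates),
#'   \code{density} (gridSize^3 array integrating to 1) and
#'   \code{crossSections} (central xy, xz and yz slices).
#' @export
density3D <- function(vectors, bandwidth = 2, gridSize = 64L, extent = 24) {
  vectors <- matrix(vectors, ncol = 3)
  if (!nrow(vectors)) stop("at least one vector is required")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  ax <- seq(-extent, extent, length.out = gridSize)
  K <- function(g, centers) {
    outer(g, centers, function(a, b) exp(-((a - b)^2) / (2 * bandwidth^2)))
  }
  Kx <- K(ax, vectors[, 1]); Ky <- K(ax, vectors[, 2])
  Kz <- K(ax, vectors[, 3])
  dens <- array(0, dim = rep(gridSize, 3))
  for (n in seq_len(nrow(vectors)))
    dens <- dens + outer(outer(Kx[, n], Ky[, n]), Kz[, n])
  voxel <- (ax[2] - ax[1])^3
  dens <- dens / (sum(dens) * voxel)
  mid <- ceiling(gridSize / 2)
  list(axes = ax, density = dens,
       crossSections = list(xy = dens[, , mid], xz = dens[, mid, ],
                            yz = dens[mid, , ]))
}

#' Wilcoxon rank sum test (two-sided)
#'
#' Exact midrank enumeration of all group assignments when the combined
#' sample size is at most 12 (the regime of per-embryo comparisons with
#' n = 6 samples per class); tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param groupA,groupB numeric vectors.
#' @return Two-sided p-value.
#' @examples
#' wilcoxonRankSum(1:3, 4:6)  # 0.1: complete separation of 3 vs 3
#' @export
wilcoxonRankSum <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 1L, length(groupB) >= 1L)
  n1 <- length(groupA); n2 <- length(groupB); n <- n1 + n2
  rk <- rank(c(groupA, groupB))
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= 12L) {
    sets <- combn(n, n1)
    Ws <- colSums(matrix(rk[sets], nrow = n1))
    mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-max(z, 0)))
  }
}
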