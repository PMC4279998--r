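# Hessian-based shape features for bright tubular structures.
#
# Eigenvalues of the Gaussian-scale Hessian, sorted ascending by signed
# value, characterize local shape: a bright tube has two strongly negative
# transverse eigenvalues and a near-zero axial one; a bright blob has three
# comparable negative eigenvalues. The linear-structure measure
# lambda_ratio = lambda2/lambda1 - lambda3/lambda1 (for all-nonpositive
# eigenvalues) is therefore high on tube axes and low on blobs and
# background, and the eigenvector of the largest eigenvalue points along
# the tube axis.

# Sampled Gaussian and derivative kernels, discretely renormalized so that
# smoothing preserves constants, the first-derivative kernel is exact on
# linear ramps and the second-derivative kernel exact on quadratics.
gaussian_kernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  m <- seq(-r, r)
  g <- exp(-m^2 / (2 * sigma^2))
  g0 <- g / sum(g)
  k1 <- m * g
  k1 <- k1 / sum(m * k1)          # sum(m * k1) == 1  -> d/dx exact on ramps
  k2 <- (m^2 - sigma^2) * g
  k2 <- k2 - mean(k2)             # zero response to constants
  k2 <- k2 * (2 / sum(m^2 * k2))  # d2/dx2 of x^2 == 2
  list(g0 = g0, g1 = k1, g2 = k2, radius = r)
}

# Correlation along one array axis with replicate edges:
# out(i) = sum_m k[m] * a(i + m).
conv_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  for (m in seq(-r, r)) {
    idx <- pmin(pmax(seq_len(n) + m, 1L), n)
    sl <- switch(axis,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + k[m + r + 1L] * sl
  }
  out
}

#' Gaussian-scale Hessian of a volume
#'
#' Estimates the six unique second derivatives of the intensity field by
#' separable Gaussian derivative filtering at a single scale, in voxel
#' units, with replicate edge handling. The result is symmetric by
#' construction.
#'
#' @param vol a [scalar_volume()].
#' @param scale Gaussian scale (standard deviation) in voxels; > 0.
#' @return A list of class `hessian_field` with 3D arrays `hxx, hyy, hzz,
#'   hxy, hxz, hyz` and the `scale` used.
#' @export
compute_hessian <- function(vol, scale = 1.0) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a single positive number")
  ker <- gaussian_kernels(scale)
  d <- dim(vol$data)
  if (any(d < 2L * ker$radius + 1L))
    stop("volume smaller than the effective derivative kernel (",
         2L * ker$radius + 1L, " voxels at scale ", scale, ")")
  a <- vol$data
  sep <- function(kx, ky, kz)
    conv_axis(conv_axis(conv_axis(a, kz, 3L), ky, 2L), kx, 1L)
  structure(list(
    hxx = sep(ker$g2, ker$g0, ker$g0),
    hyy = sep(ker$g0, ker$g2, ker$g0),
    hzz = sep(ker$g0, ker$g0, ker$g2),
    hxy = sep(ker$g1, ker$g1, ker$g0),
    hxz = sep(ker$g1, ker$g0, ker$g1),
    hyz = sep(ker$g0, ker$g1, ker$g1),
    scale = scale
  ), class = "hessian_field")
}

#' Per-voxel eigendecomposition of a Hessian field
#'
#' @param hessian a `hessian_field` from [compute_hessian()].
#' @return List with `values`: 4D array `(nx, ny, nz, 3)` of eigenvalues
#'   ascending by signed value (lambda1 <= lambda2 <= lambda3), and `e3`:
#'   4D array `(nx, ny, nz, 3)` holding the unit eigenvector of lambda3
#'   (the tube-axis direction on bright tubes; sign is arbitrary).
#' @export
eigen_decompose <- function(hessian) {
  stopifnot(inherits(hessian, "hessian_field"))
  comps <- hessian[c("hxx", "hyy", "hzz", "hxy", "hxz", "hyz")]
  if (any(vapply(comps, function(x) any(!is.finite(x)), logical(1))))
    stop("non-finite entries in Hessian field")
  d <- dim(hessian$hxx)
  res <- hessian_eigen_cpp(as.vector(hessian$hxx), as.vector(hessian$hyy),
                           as.vector(hessian$hzz), as.vector(hessian$hxy),
                           as.vector(hessian$hxz), as.vector(hessian$hyz))
  list(values = array(res$values, c(d, 3L)),
       e3 = array(res$e3, c(d, 3L)))
}

#' Linear-structure measure from sorted Hessian eigenvalues
#'
#' For bright-on-dark structures (all eigenvalues <= 0) the measure is
#' `lambda2/lambda1 - lambda3/lambda1`: near 1 on tube axes (two equal
#' negative transverse curvatures, zero axial), near 0 on blobs (three
#' comparable curvatures). When only the first two eigenvalues are
#' non-positive it falls back to `lambda2/lambda1`, and it is 0 otherwise —
#' in particular on voxels darker than their surroundings, which have
#' positive leading eigenvalues. `lambda1 == 0` implies all three are 0 and
#' maps to 0.
#'
#' @param lambda1,lambda2,lambda3 numeric vectors of eigenvalues sorted
#'   ascending by signed value.
#' @return Numeric vector in \[0, 1\].
#' @export
lambda_ratio <- function(lambda1, lambda2, lambda3) {
  if (any(lambda1 > lambda2 + 1e-12) || any(lambda2 > lambda3 + 1e-12))
    stop("eigenvalues must satisfy lambda1 <= lambda2 <= lambda3")
  out <- numeric(length(lambda1))
  neg1 <- lambda1 < 0
  b1 <- neg1 & lambda3 <= 0
  b2 <- neg1 & lambda2 <= 0 & lambda3 > 0
  out[b1] <- lambda2[b1] / lambda1[b1] - lambda3[b1] / lambda1[b1]
  out[b2] <- lambda2[b2] / lambda1[b2]
  out
}

#' Corrected axis eigenvector
#'
#' Passes the third eigenvector through only where the two leading
#' eigenvalues are non-positive (bright local structure); elsewhere it is
#' zeroed, so voxels darker than the background never carry an orientation
#' and can never be pulled toward a reference structure by the orientation
#' metric.
#'
#' @param lambda1,lambda2 numeric vectors of the two smallest eigenvalues.
#' @param e3 matrix `n x 3` (or length-3 vector) of unit eigenvectors.
#' @return Matrix `n x 3`; each row is `e3` or exactly zero.
#' @export
corrected_e3 <- function(lambda1, lambda2, e3) {
  if (is.null(dim(e3))) e3 <- matrix(e3, ncol = 3L)
  keep <- lambda1 <= lambda2 & lambda2 <= 0
  e3 * as.numeric(keep)
}

#' Build the per-voxel feature volume
#'
#' Runs the full feature pipeline on a normalized volume: Gaussian-scale
#' Hessian, per-voxel eigendecomposition, the linear-structure measure,
#' and the corrected axis eigenvector; then estimates the metric context
#' over all voxels: the population standard deviation of the
#' linear-structure measure and the covariance matrix of the selected
#' feature channels, diagonally regularized until invertible.
#'
#' @param vol a [scalar_volume()], intensities expected in \[0, 1\].
#' @param scale Hessian Gaussian scale in voxels (default 1).
#' @param channel_spec character vector naming the channels of the feature
#'   vector C(x) used by the Mahalanobis and inner-product metrics; any of
#'   `"lambda_ratio"` (1 column), `"e3"` (3 columns), `"intensity"`
#'   (1 column). Default `c("lambda_ratio", "e3")`.
#' @return An object of class `feature_volume` with fields `lambda_ratio`
#'   (3D array), `e3` (4D array, corrected), `eigenvalues` (4D array),
#'   `channels` (voxels x k matrix), `covariance`, `sigma_lambda`, `scale`,
#'   `dim`, `spacing`.
#' @export
build_feature_volume <- function(vol, scale = 1.0,
                                 channel_spec = c("lambda_ratio", "e3")) {
  stopifnot(inherits(vol, "scalar_volume"))
  known <- c("lambda_ratio", "e3", "intensity")
  if (length(channel_spec) < 1L || !all(channel_spec %in% known))
    stop("channel_spec must be a non-empty subset of: ",
         paste(known, collapse = ", "))
  d <- dim(vol$data)
  eig <- eigen_decompose(compute_hessian(vol, scale))
  ev <- matrix(eig$values, ncol = 3L)
  e3m <- matrix(eig$e3, ncol = 3L)
  lr <- lambda_ratio(ev[, 1], ev[, 2], ev[, 3])
  e3c <- corrected_e3(ev[, 1], ev[, 2], e3m)
  cols <- list(lambda_ratio = lr, e3 = e3c, intensity = as.vector(vol$data))
  channels <- do.call(cbind, cols[channel_spec])
  colnames(channels) <- unlist(lapply(channel_spec, function(nm)
    if (nm == "e3") c("e3x", "e3y", "e3z") else nm))
  V <- cov(channels)
  V <- regularize_covariance(V)
  structure(list(
    lambda_ratio = array(lr, d),
    e3 = array(e3c, c(d, 3L)),
    eigenvalues = array(ev, c(d, 3L)),
    channels = channels,
    covariance = V,
    sigma_lambda = sqrt(mean((lr - mean(lr))^2)),
    scale = scale,
    dim = d,
    spacing = vol$spacing
  ), class = "feature_volume")
}

# Add epsilon = 1e-6 * trace/n to the diagonal, doubling until the matrix
# is numerically invertible. Deterministic and mask-free.
regularize_covariance <- function(V) {
  n <- nrow(V)
  eps <- 1e-6 * max(sum(diag(V)) / n, .Machine$double.eps)
  for (i in 1:60) {
    Vr <- V + diag(eps, n)
    ok <- tryCatch({ solve(Vr); TRUE },
                   error = function(e) FALSE)
    if (ok && rcond(Vr) > 1e-14) return(Vr)
    eps <- eps * 2
  }
  stop("covariance could not be regularized to invertibility")
}

#' @export
print.feature_volume <- function(x, ...) {
  cat(sprintf(
    "feature_volume: %d x %d x %d voxels, scale %g, channels [%s], sigma(lambda_ratio) = %.4g\n",
    x$dim[1], x$dim[2], x$dim[3], x$scale,
    paste(colnames(x$channels), collapse = ", "), x$sigma_lambda))
  invisible(x)
}
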