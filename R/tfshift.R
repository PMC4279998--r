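# The localized transfer-function shift.
#
# One edit is: a reference voxel x0 (an exemplar of the structure the user
# wants to see), a set of brushed sphere centers defining the region of
# interest Omega, a feature-sensitivity alpha, a radius beta, and a choice
# of feature dissimilarity d_F. The per-voxel shift is
#
#   Delta(x) = (I(x0) - I(x)) * exp(-alpha * d_F(x, x0)) /
#              (1 + exp(d_E(x, Omega) - beta))
#
# so a voxel whose features match the reference and which lies inside the
# brushed region has its intensity shifted toward I(x0) before the preset
# lookup. The factor (I(x0) - I(x)) guarantees the identity condition:
# voxels already at the reference intensity are never changed.

#' Construct an edit operation
#'
#' @param x0 numeric length-3 reference position, 1-based voxel
#'   coordinates (fractional allowed).
#' @param stroke_centers matrix `k x 3` (or length-3 vector) of brushed
#'   pointer centers defining the region of interest, voxel coordinates.
#' @param alpha feature sensitivity, >= 0. Larger alpha restricts the edit
#'   to voxels whose features closely match the reference; 0 shifts
#'   everything inside the region regardless of features.
#' @param beta region radius, >= 0, in x-voxel units (distances are scaled
#'   per axis by `spacing/spacing_x`). The locality weight is 0.5 at
#'   distance beta from the nearest stroke center.
#' @param metric one of `"orientation"`, `"lambda_ratio"`,
#'   `"mahalanobis"`, `"dot"`.
#' @param bounds optional volume dimensions; when given, `x0` and all
#'   stroke centers are checked to lie inside `[1, bounds]`.
#' @return An object of class `edit_operation`.
#' @export
edit_operation <- function(x0, stroke_centers, alpha, beta,
                           metric = c("orientation", "lambda_ratio",
                                      "mahalanobis", "dot"),
                           bounds = NULL) {
  metric <- match.arg(metric)
  x0 <- as.numeric(x0)
  if (length(x0) != 3L || any(!is.finite(x0))) stop("`x0` must be a finite 3-vector")
  if (is.null(dim(stroke_centers)))
    stroke_centers <- matrix(as.numeric(stroke_centers), ncol = 3L, byrow = TRUE)
  stroke_centers <- as.matrix(stroke_centers)
  if (ncol(stroke_centers) != 3L || nrow(stroke_centers) < 1L)
    stop("`stroke_centers` must be a non-empty k x 3 matrix")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a single number >= 0")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("`beta` must be a single number >= 0")
  if (!is.null(bounds)) {
    pts <- rbind(x0, stroke_centers)
    if (any(pts < 1 | pts > rep(bounds, each = nrow(pts))))
      stop("x0 / stroke centers fall outside the volume bounds")
  }
  structure(list(x0 = x0, stroke_centers = stroke_centers,
                 alpha = alpha, beta = beta, metric = metric),
            class = "edit_operation")
}

#' @export
print.edit_operation <- function(x, ...) {
  cat(sprintf(
    "edit_operation: x0 = (%g, %g, %g), %d stroke center(s), alpha = %g, beta = %g, metric = %s\n",
    x$x0[1], x$x0[2], x$x0[3], nrow(x$stroke_centers), x$alpha, x$beta, x$metric))
  invisible(x)
}

#' Mahalanobis feature dissimilarity
#'
#' `sqrt((C(x) - C(x0))^T V^-1 (C(x) - C(x0)))` with V the covariance of
#' the feature channels over the volume.
#'
#' @param c_x feature vector, or matrix with one feature vector per row.
#' @param c_x0 reference feature vector.
#' @param V feature covariance matrix (invertible; see
#'   [build_feature_volume()], which regularizes it).
#' @return Non-negative numeric vector.
#' @export
dissim_mahalanobis <- function(c_x, c_x0, V) {
  if (is.null(dim(c_x))) c_x <- matrix(c_x, nrow = 1L)
  if (ncol(c_x) != length(c_x0) || ncol(c_x) != nrow(V))
    stop("feature vector / covariance dimensions disagree")
  Vinv <- solve(V)
  diff <- sweep(c_x, 2L, c_x0)
  sqrt(pmax(rowSums((diff %*% Vinv) * diff), 0))
}

#' Inner-product feature dissimilarity
#'
#' `1 - C(x) . C(x0)` for unit feature vectors. Inputs that are not unit
#' length are normalized first (zero vectors are left at zero, giving the
#' maximal dissimilarity of 1 against any unit reference).
#'
#' @param c_x feature vector or matrix of row vectors.
#' @param c_x0 reference feature vector.
#' @return Numeric vector (0 for identical unit vectors, 2 for
#'   antiparallel).
#' @export
dissim_dot <- function(c_x, c_x0) {
  if (is.null(dim(c_x))) c_x <- matrix(c_x, nrow = 1L)
  c_x <- normalize_rows(c_x)
  c_x0 <- as.numeric(normalize_rows(matrix(c_x0, nrow = 1L)))
  1 - as.numeric(c_x %*% c_x0)
}

#' Orientation dissimilarity
#'
#' `1 - |e3'(x) . e3'(x0)|` on corrected axis eigenvectors: 0 for parallel
#' or antiparallel axes (the eigenvector sign is arbitrary), 1 for
#' orthogonal axes. A zero vector — a voxel whose orientation was
#' suppressed because it shows no bright local structure — returns the
#' maximal dissimilarity 1. The admission region `d_F <= 0.5` is exactly
#' the set of axes within 60 degrees of the reference.
#'
#' @param e3_x unit (or zero) 3-vector, or matrix of row vectors.
#' @param e3_x0 unit (or zero) reference 3-vector.
#' @return Numeric vector in \[0, 1\].
#' @export
dissim_orientation <- function(e3_x, e3_x0) {
  if (is.null(dim(e3_x))) e3_x <- matrix(e3_x, nrow = 1L)
  1 - abs(as.numeric(e3_x %*% as.numeric(e3_x0)))
}

#' Linear-structure-measure dissimilarity
#'
#' The 1D standardized distance `|lr(x) - lr(x0)| / sigma`, with sigma the
#' standard deviation of the measure over the volume.
#'
#' @param lr_x numeric vector of linear-structure measures.
#' @param lr_x0 reference value.
#' @param sigma standard deviation, > 0.
#' @return Non-negative numeric vector.
#' @export
dissim_lambda_ratio <- function(lr_x, lr_x0, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  abs(lr_x - lr_x0) / sigma
}

#' Feature-sensitivity weight
#'
#' `exp(-alpha * d_F)`: 1 when the features match the reference exactly
#' (or alpha = 0), decaying with dissimilarity at a rate set by alpha.
#'
#' @param d_f non-negative dissimilarity.
#' @param alpha sensitivity, >= 0.
#' @return Numeric in (0, 1\].
#' @export
feature_weight <- function(d_f, alpha) exp(-alpha * d_f)

#' Spatial locality weight
#'
#' Logistic fall-off `1 / (1 + exp(d_E - beta))`: 0.5 at distance beta
#' from the region's stroke centers, ~1 deep inside, vanishing outside
#' (below 1e-8 beyond beta + 20).
#'
#' @param d_e non-negative distance to the region.
#' @param beta region radius, >= 0.
#' @return Numeric in (0, 1).
#' @export
locality_weight <- function(d_e, beta) 1 / (1 + exp(d_e - beta))

#' Distance to the brushed region
#'
#' Minimum over stroke centers of the Euclidean distance, in voxel units
#' scaled per axis by `spacing/spacing[1]` so that anisotropic stacks keep
#' physically round regions while beta stays an x-voxel-scale number. A
#' single center reduces to the plain pointer-center distance.
#'
#' @param x position matrix `n x 3` (or length-3 vector), voxel
#'   coordinates.
#' @param stroke_centers matrix `k x 3` of centers.
#' @param spacing per-axis spacing in um.
#' @return Non-negative numeric vector of length `n`.
#' @export
roi_distance <- function(x, stroke_centers, spacing = c(1, 1, 1)) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(dim(stroke_centers)))
    stroke_centers <- matrix(stroke_centers, ncol = 3L, byrow = TRUE)
  if (nrow(stroke_centers) < 1L) stop("`stroke_centers` must be non-empty")
  s <- spacing / spacing[1]
  d2 <- NULL
  for (k in seq_len(nrow(stroke_centers))) {
    dk <- ((x[, 1] - stroke_centers[k, 1]) * s[1])^2 +
          ((x[, 2] - stroke_centers[k, 2]) * s[2])^2 +
          ((x[, 3] - stroke_centers[k, 3]) * s[3])^2
    d2 <- if (is.null(d2)) dk else pmin(d2, dk)
  }
  sqrt(d2)
}

normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  pos <- nrm > 0
  m[pos, ] <- m[pos, , drop = FALSE] / nrm[pos]
  m
}

# Grid of 1-based voxel coordinates as an n x 3 matrix, x fastest.
voxel_grid <- function(d) {
  cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2])
  )
}

# Per-voxel feature dissimilarity to the reference voxel for one metric.
feature_dissimilarity <- function(features, edit) {
  i0 <- round(edit$x0)
  d <- features$dim
  if (any(i0 < 1 | i0 > d)) stop("reference point x0 outside the volume")
  lin0 <- i0[1] + d[1] * ((i0[2] - 1) + d[2] * (i0[3] - 1))
  switch(edit$metric,
    orientation = {
      E <- matrix(features$e3, ncol = 3L)
      e0 <- E[lin0, ]
      if (all(e0 == 0)) {
        warning("reference point has no defined orientation (suppressed ",
                "axis eigenvector); d_F = 1 everywhere")
        rep(1, nrow(E))
      } else {
        pmin(pmax(dissim_orientation(E, e0), 0), 1)
      }
    },
    lambda_ratio = {
      lr <- as.vector(features$lambda_ratio)
      dissim_lambda_ratio(lr, lr[lin0], features$sigma_lambda)
    },
    mahalanobis = {
      if (is.null(features$channels) || ncol(features$channels) < 1L)
        stop("Mahalanobis metric requires feature channels")
      dissim_mahalanobis(features$channels, features$channels[lin0, ],
                         features$covariance)
    },
    dot = {
      Cn <- normalize_rows(features$channels)
      dissim_dot(Cn, Cn[lin0, ])
    })
}

#' Compute the per-voxel transfer-function shift field
#'
#' Evaluates `Delta(x) = (I(x0) - I(x)) * exp(-alpha * d_F) /
#' (1 + exp(d_E - beta))` at every voxel. `I(x0)` is trilinearly
#' interpolated at the (possibly fractional) reference position; feature
#' values for the reference are read at the nearest voxel. Voxels at the
#' reference intensity get a shift of exactly zero, and the shift vanishes
#' outside the brushed region.
#'
#' @param vol a [scalar_volume()] (the same preprocessed volume features
#'   were built from).
#' @param features a [build_feature_volume()] result on the same grid.
#' @param edit an [edit_operation()].
#' @return An object of class `shift_field` with `delta` (3D array),
#'   `spacing`, and `provenance` (list of edits).
#' @export
compute_shift_field <- function(vol, features, edit) {
  stopifnot(inherits(vol, "scalar_volume"),
            inherits(features, "feature_volume"),
            inherits(edit, "edit_operation"))
  d <- dim(vol$data)
  if (!identical(d, features$dim))
    stop("volume and feature grids disagree")
  pts <- rbind(edit$x0, edit$stroke_centers)
  if (any(pts < 1 | pts > rep(d, each = nrow(pts))))
    stop("x0 / stroke centers fall outside the volume bounds")
  I0 <- trilinear_interp(vol$data, matrix(edit$x0, nrow = 1L))
  d_f <- feature_dissimilarity(features, edit)
  d_e <- roi_distance(voxel_grid(d), edit$stroke_centers, vol$spacing)
  g <- feature_weight(d_f, edit$alpha) * locality_weight(d_e, edit$beta)
  delta <- (I0 - as.vector(vol$data)) * g
  structure(list(delta = array(delta, d), spacing = vol$spacing,
                 provenance = list(edit)),
            class = "shift_field")
}

#' Combine saved shift fields
#'
#' Voxelwise sum of the shifts of several edits; any clamping happens only
#' at transfer-function evaluation, so combination is linear and
#' order-independent and each edit's locality is preserved. An empty list
#' is invalid (there is no grid to define a zero field on); pass a single
#' field to get it back unchanged.
#'
#' @param fields list of `shift_field` objects on the same grid.
#' @return A `shift_field` with concatenated provenance.
#' @export
combine_shift_fields <- function(fields) {
  if (!is.list(fields) || length(fields) < 1L)
    stop("`fields` must be a non-empty list of shift fields")
  stopifnot(all(vapply(fields, inherits, logical(1), "shift_field")))
  d <- dim(fields[[1]]$delta)
  delta <- array(0, d)
  prov <- list()
  for (f in fields) {
    if (!identical(dim(f$delta), d)) stop("shift fields on different grids")
    delta <- delta + f$delta
    prov <- c(prov, f$provenance)
  }
  structure(list(delta = delta, spacing = fields[[1]]$spacing,
                 provenance = prov),
            class = "shift_field")
}

#' @export
print.shift_field <- function(x, ...) {
  d <- dim(x$delta)
  cat(sprintf(
    "shift_field: %d x %d x %d voxels, %d edit(s), range [%.4g, %.4g]\n",
    d[1], d[2], d[3], length(x$provenance), min(x$delta), max(x$delta)))
  invisible(x)
}
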