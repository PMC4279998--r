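# Seeded synthetic scenes emulating two-photon stacks of crossing
# dendritic/axonal tubes: bright Gaussian-profile tubes in two orientation
# families running in the xy plane, an axis-aligned box in which
# intensities are attenuated (the low-contrast region under a blood
# vessel), optional spheres (soma-like blobs), and additive Gaussian
# noise. Gaussian radial profiles stand in for PSF blur and keep the
# Hessian features well-posed.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Squared distance from every voxel center to the infinite line through
# `point` with unit direction `u`, as a 3D array.
line_dist2 <- function(shape, point, u) {
  gx <- seq_len(shape[1]) - point[1]
  gy <- seq_len(shape[2]) - point[2]
  gz <- seq_len(shape[3]) - point[3]
  # |p|^2 - (p . u)^2, built separably
  px2 <- array(rep(gx^2, times = shape[2] * shape[3]), shape)
  py2 <- array(rep(rep(gy^2, each = shape[1]), times = shape[3]), shape)
  pz2 <- array(rep(gz^2, each = shape[1] * shape[2]), shape)
  pu <- array(rep(gx * u[1], times = shape[2] * shape[3]), shape) +
        array(rep(rep(gy * u[2], each = shape[1]), times = shape[3]), shape) +
        array(rep(gz * u[3], each = shape[1] * shape[2]), shape)
  pmax(px2 + py2 + pz2 - pu^2, 0)
}

#' Synthesize a straight Gaussian-profile tube
#'
#' Intensity `peak * exp(-dist^2 / (2 radius^2))` of the voxel-center
#' distance to the tube's axis line; the mask covers voxels within two
#' radii of the axis.
#'
#' @param shape grid dimensions `c(nx, ny, nz)`.
#' @param point a point on the axis, voxel coordinates.
#' @param direction axis direction (any nonzero 3-vector; normalized).
#' @param radius Gaussian radius in voxels, > 0.
#' @param peak on-axis intensity in (0, 1].
#' @return List with `volume` (a noiseless [scalar_volume()]) and `mask`
#'   (logical array, distance <= 2 * radius).
#' @export
make_tube <- function(shape, point, direction, radius, peak = 0.9) {
  n2 <- sum(direction^2)
  if (!is.finite(n2) || n2 == 0) stop("`direction` must be nonzero")
  if (radius <= 0) stop("`radius` must be > 0")
  if (peak <= 0 || peak > 1) stop("`peak` must be in (0, 1]")
  u <- direction / sqrt(n2)
  d2 <- line_dist2(shape, point, u)
  list(volume = scalar_volume(peak * exp(-d2 / (2 * radius^2)),
                              intensity_domain = c(0, 1)),
       mask = d2 <= (2 * radius)^2)
}

#' Synthesize a Gaussian-profile sphere
#'
#' Soma-like blob: `peak * exp(-|x - center|^2 / (2 radius^2))`. Its
#' isotropic Hessian at the center makes the linear-structure measure
#' vanish there, which is what lets tube-selective edits leave somata
#' alone.
#'
#' @param shape grid dimensions.
#' @param center sphere center, voxel coordinates.
#' @param radius Gaussian radius in voxels, > 0.
#' @param peak center intensity in (0, 1].
#' @return List with `volume` and `mask` as in [make_tube()].
#' @export
make_sphere <- function(shape, center, radius, peak = 0.9) {
  if (radius <= 0) stop("`radius` must be > 0")
  if (peak <= 0 || peak > 1) stop("`peak` must be in (0, 1]")
  gx <- (seq_len(shape[1]) - center[1])^2
  gy <- (seq_len(shape[2]) - center[2])^2
  gz <- (seq_len(shape[3]) - center[3])^2
  d2 <- array(rep(gx, times = shape[2] * shape[3]), shape) +
        array(rep(rep(gy, each = shape[1]), times = shape[3]), shape) +
        array(rep(gz, each = shape[1] * shape[2]), shape)
  list(volume = scalar_volume(peak * exp(-d2 / (2 * radius^2)),
                              intensity_domain = c(0, 1)),
       mask = d2 <= (2 * radius)^2)
}

#' Generate a crossing-tube phantom scene
#'
#' Draws `n_tubes_per_family` straight tubes for each of two orientation
#' families (default along (1, 1, 0) and (1, -1, 0), i.e. crisscrossing in
#' the xy plane), combines them by voxelwise maximum, attenuates
#' intensities inside an axis-aligned shadow box (emulating the
#' low-contrast region directly below a blood vessel), then adds zero-mean
#' Gaussian noise and clips to \[0, 1\]. Tube axis points are drawn from
#' the seeded RNG inside the central half of the grid; the same seed
#' always reproduces the identical scene.
#'
#' @param shape grid dimensions (default 96^3).
#' @param n_tubes_per_family tubes per orientation family (default 4).
#' @param family_dirs 2 x 3 matrix of family axis directions (must not be
#'   parallel).
#' @param radius Gaussian tube radius in voxels (default 2).
#' @param peaks length-2 peak intensities per family; the default makes
#'   family A bright (0.9) and family B low-contrast (0.45).
#' @param shadow_box 2 x 3 matrix `rbind(lo, hi)` of the attenuated box in
#'   voxel coordinates, or `NULL` for the default band spanning the
#'   central-right x range; `NA` entries extend to the volume face.
#' @param shadow_factor multiplicative attenuation in (0, 1) applied
#'   inside the box before noise (default 0.4).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 0.02).
#' @param seed RNG seed recorded in the scene (default 1).
#' @return An object of class `phantom_scene` with `volume`
#'   ([scalar_volume()]), `labels` (integer array, 0 = background,
#'   otherwise the id of the locally dominant tube), `structures` (per-id
#'   metadata: kind, family, point, direction, radius, peak),
#'   `shadow_mask` (logical array), and `seed`.
#' @export
make_crossing_scene <- function(shape = c(96, 96, 96),
                                n_tubes_per_family = 4,
                                family_dirs = rbind(c(1, 1, 0), c(1, -1, 0)),
                                radius = 2,
                                peaks = c(0.9, 0.45),
                                shadow_box = NULL,
                                shadow_factor = 0.4,
                                noise_sd = 0.02,
                                seed = 1) {
  family_dirs <- as.matrix(family_dirs)
  u1 <- family_dirs[1, ] / sqrt(sum(family_dirs[1, ]^2))
  u2 <- family_dirs[2, ] / sqrt(sum(family_dirs[2, ]^2))
  if (abs(abs(sum(u1 * u2)) - 1) < 1e-9)
    stop("family directions must not be parallel")
  if (!is.null(shadow_factor) && (shadow_factor <= 0 || shadow_factor >= 1))
    stop("`shadow_factor` must be in (0, 1)")
  if (is.null(shadow_box))
    shadow_box <- rbind(c(0.55 * shape[1], NA, NA),
                        c(0.85 * shape[1], NA, NA))
  shadow_box[1, ][is.na(shadow_box[1, ])] <- 1
  shadow_box[2, ][is.na(shadow_box[2, ])] <- shape[is.na(shadow_box[2, ])]
  dirs <- rbind(u1, u2)
  with_local_seed(seed, {
    intensity <- array(0, shape)
    labels <- array(0L, shape)
    best <- array(-Inf, shape)  # argmax bookkeeping over tube intensities
    structures <- list()
    id <- 0L
    for (fam in seq_len(if (n_tubes_per_family > 0) 2L else 0L)) {
      for (t in seq_len(n_tubes_per_family)) {
        id <- id + 1L
        point <- c(runif(1, 0.25, 0.75) * shape[1],
                   runif(1, 0.25, 0.75) * shape[2],
                   runif(1, 0.25, 0.75) * shape[3])
        tube <- make_tube(shape, point, dirs[fam, ], radius, peaks[fam])
        iv <- tube$volume$data
        intensity <- pmax(intensity, iv)
        win <- tube$mask & (iv > best)  # strict: ties keep the lower id
        labels[win] <- id
        best[win] <- iv[win]
        structures[[id]] <- list(kind = "tube", family = fam, point = point,
                                 direction = dirs[fam, ], radius = radius,
                                 peak = peaks[fam])
      }
    }
    shadow_mask <- array(FALSE, shape)
    shadow_mask[seq(max(1, ceiling(shadow_box[1, 1])), min(shape[1], floor(shadow_box[2, 1]))),
                seq(max(1, ceiling(shadow_box[1, 2])), min(shape[2], floor(shadow_box[2, 2]))),
                seq(max(1, ceiling(shadow_box[1, 3])), min(shape[3], floor(shadow_box[2, 3])))] <- TRUE
    intensity[shadow_mask] <- intensity[shadow_mask] * shadow_factor
    if (noise_sd > 0)
      intensity <- intensity + array(rnorm(prod(shape), 0, noise_sd), shape)
    intensity <- pmin(pmax(intensity, 0), 1)
    structure(list(volume = scalar_volume(intensity, intensity_domain = c(0, 1)),
                   labels = labels, structures = structures,
                   shadow_mask = shadow_mask, seed = seed),
              class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf(
    "phantom_scene: %d x %d x %d voxels, %d structure(s), seed %s\n",
    d[1], d[2], d[3], length(x$structures), format(x$seed)))
  invisible(x)
}

#' Voxels on (or near) a tube's axis
#'
#' Convenience accessor for validation harnesses: voxel-center positions
#' within `tol` voxels of the axis line of structure `id`, restricted to
#' the interior margin.
#'
#' @param scene a `phantom_scene`.
#' @param id structure id.
#' @param tol axis distance tolerance in voxels (default 0.5).
#' @param margin interior margin in voxels excluded at the faces
#'   (default 4).
#' @return Integer matrix `n x 3` of voxel coordinates.
#' @export
axis_voxels <- function(scene, id, tol = 0.5, margin = 4) {
  st <- scene$structures[[id]]
  shape <- dim(scene$volume$data)
  d2 <- line_dist2(shape, st$point, st$direction)
  idx <- which(d2 <= tol^2, arr.ind = TRUE)
  keep <- idx[, 1] > margin & idx[, 1] <= shape[1] - margin &
          idx[, 2] > margin & idx[, 2] <= shape[2] - margin &
          idx[, 3] > margin & idx[, 3] <= shape[3] - margin
  unname(idx[keep, , drop = FALSE])
}
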