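# CPU orthographic ray caster with front-to-back emission-absorption
# compositing. All rays are marched in lockstep, one vectorized
# trilinear-interpolation + transfer-function lookup + compositing update
# per sample plane, which keeps the cost per step independent of image
# size bookkeeping.

# Trilinear interpolation of a 3D array at fractional 1-based coordinates.
# Coordinates are clamped to [1, n] per axis (replicate behavior at the
# faces); callers mask samples outside the volume's bounding box.
trilinear_interp <- function(a, p) {
  d <- dim(a)
  px <- pmin(pmax(p[, 1], 1), d[1])
  py <- pmin(pmax(p[, 2], 1), d[2])
  pz <- pmin(pmax(p[, 3], 1), d[3])
  x0 <- pmax(pmin(floor(px), d[1] - 1L), 1L)
  y0 <- pmax(pmin(floor(py), d[2] - 1L), 1L)
  z0 <- pmax(pmin(floor(pz), d[3] - 1L), 1L)
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  v000 <- a[cbind(x0, y0, z0)]; v100 <- a[cbind(x1, y0, z0)]
  v010 <- a[cbind(x0, y1, z0)]; v110 <- a[cbind(x1, y1, z0)]
  v001 <- a[cbind(x0, y0, z1)]; v101 <- a[cbind(x1, y0, z1)]
  v011 <- a[cbind(x0, y1, z1)]; v111 <- a[cbind(x1, y1, z1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Rendering settings
#'
#' @param eye_direction length-3 viewing direction (the direction rays
#'   travel); need not be unit length, must be nonzero. Axis-aligned
#'   directions such as `c(0, 0, -1)` reproduce the usual top-down stack
#'   view.
#' @param image_size `c(width, height)` in pixels, or `NULL` to use one
#'   pixel per voxel of the projected extent (for axis-aligned views this
#'   makes pixel (i, j) the column through voxel (i, j)).
#' @param step ray sampling interval in voxel units, > 0.
#' @param reference_step step at which the preset's opacities are defined;
#'   per-sample opacity is corrected as `1 - (1 - a)^(step/reference_step)`.
#' @param background RGBA composited behind the volume.
#' @param early_termination_alpha accumulated-opacity cutoff in (0, 1];
#'   a ray stops accumulating once its opacity reaches this value.
#' @return An object of class `render_settings`.
#' @export
render_settings <- function(eye_direction = c(0, 0, -1), image_size = NULL,
                            step = 0.5, reference_step = 1.0,
                            background = c(0, 0, 0, 1),
                            early_termination_alpha = 0.99) {
  eye_direction <- as.numeric(eye_direction)
  n2 <- sum(eye_direction^2)
  if (length(eye_direction) != 3L || !is.finite(n2) || n2 == 0)
    stop("`eye_direction` must be a nonzero 3-vector")
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0")
  if (!is.numeric(reference_step) || reference_step <= 0)
    stop("`reference_step` must be > 0")
  if (early_termination_alpha <= 0 || early_termination_alpha > 1)
    stop("`early_termination_alpha` must be in (0, 1]")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background < 0) || any(background > 1))
    stop("`background` must be RGBA in [0, 1]")
  structure(list(eye_direction = eye_direction / sqrt(n2),
                 image_size = image_size, step = step,
                 reference_step = reference_step, background = background,
                 early_termination_alpha = early_termination_alpha),
            class = "render_settings")
}

# Orthonormal camera basis (u = image x, v = image y, w = ray direction).
# u and v start from the two world axes other than the dominant axis of w
# (in axis order) and are Gram-Schmidt orthogonalized, so axis-aligned
# views use exact world axes and axis permutations of the scene permute
# the image accordingly.
camera_basis <- function(eye) {
  w <- eye / sqrt(sum(eye^2))
  k <- which.max(abs(w))
  others <- setdiff(1:3, k)
  u <- numeric(3); u[others[1]] <- 1
  v <- numeric(3); v[others[2]] <- 1
  u <- u - sum(u * w) * w
  u <- u / sqrt(sum(u^2))
  v <- v - sum(v * w) * w - sum(v * u) * u
  v <- v / sqrt(sum(v^2))
  list(u = u, v = v, w = w)
}

# Shared ray geometry for render_volume() and pick_voxel(): pixel-plane
# ranges over the projections of the volume's bounding box (voxel centers
# padded by half a voxel) and the sample t-range along the ray direction.
ray_geometry <- function(d, settings) {
  basis <- camera_basis(settings$eye_direction)
  corners <- as.matrix(expand.grid(c(0.5, d[1] + 0.5), c(0.5, d[2] + 0.5),
                                   c(0.5, d[3] + 0.5)))
  ru <- range(corners %*% basis$u)
  rv <- range(corners %*% basis$v)
  rt <- range(corners %*% basis$w)
  size <- settings$image_size
  if (is.null(size)) size <- c(max(1L, round(diff(ru))), max(1L, round(diff(rv))))
  list(basis = basis, ru = ru, rv = rv, rt = rt,
       width = as.integer(size[1]), height = as.integer(size[2]))
}

# Pixel-center coordinates (s_u, s_v) in the camera plane.
pixel_plane_coords <- function(geom, i, j) {
  cbind(geom$ru[1] + (i - 0.5) * diff(geom$ru) / geom$width,
        geom$rv[1] + (j - 0.5) * diff(geom$rv) / geom$height)
}

#' Composite one ray front to back
#'
#' Reference implementation of the per-ray emission-absorption recurrence
#' used by [render_volume()]: opacity correction
#' `a' = 1 - (1 - a)^(step/reference_step)`, then
#' `C <- C + (1 - A) a' c`, `A <- A + (1 - A) a'`, stopping once `A`
#' reaches `early_termination_alpha`, and finally compositing the
#' background behind the accumulated color.
#'
#' @param samples matrix `n x 4` of RGBA samples ordered front to back
#'   (may have 0 rows).
#' @param step sampling interval the samples were taken at.
#' @param reference_step opacity reference step.
#' @param background RGBA composited behind the samples.
#' @param early_termination_alpha accumulation cutoff in (0, 1].
#' @return RGBA vector of length 4.
#' @export
composite_ray <- function(samples, step, reference_step = 1.0,
                          background = c(0, 0, 0, 0),
                          early_termination_alpha = 1.0) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 4L)
  C <- c(0, 0, 0); A <- 0
  for (i in seq_len(nrow(samples))) {
    if (A >= early_termination_alpha) break
    a <- 1 - (1 - samples[i, 4])^(step / reference_step)
    w <- (1 - A) * a
    C <- C + w * samples[i, 1:3]
    A <- A + w
  }
  C <- C + (1 - A) * background[4] * background[1:3]
  A <- A + (1 - A) * background[4]
  c(C, A)
}

#' Render a volume by orthographic ray casting
#'
#' Casts one parallel ray per pixel along the eye direction, trilinearly
#' interpolates the intensity (and, when given, the shift field) at fixed
#' intervals, evaluates the shifted transfer function per sample, and
#' composites front to back under the emission-absorption model. Passing
#' `shift = NULL` (or an all-zero field) renders the unmodified preset.
#'
#' @param vol a [scalar_volume()].
#' @param tf a [transfer_function()].
#' @param shift optional `shift_field` on the same grid.
#' @param settings a [render_settings()].
#' @return An `rgba_image`: numeric array `(width, height, 4)` indexed
#'   `[i, j, channel]` with image x = camera u and image y = camera v.
#' @export
render_volume <- function(vol, tf, shift = NULL,
                          settings = render_settings()) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(tf, "transfer_function"),
            inherits(settings, "render_settings"))
  d <- dim(vol$data)
  if (!is.null(shift)) {
    stopifnot(inherits(shift, "shift_field"))
    if (!identical(dim(shift$delta), d))
      stop("shift field grid does not match the volume")
  }
  geom <- ray_geometry(d, settings)
  W <- geom$width; H <- geom$height
  npx <- W * H
  px <- pixel_plane_coords(geom,
                           rep(seq_len(W), times = H),
                           rep(seq_len(H), each = W))
  base <- px[, 1] %o% geom$basis$u + px[, 2] %o% geom$basis$v
  ts <- seq(geom$rt[1] + settings$step / 2, geom$rt[2], by = settings$step)
  C <- matrix(0, npx, 3L); A <- numeric(npx)
  dom <- vol$intensity_domain
  expo <- settings$step / settings$reference_step
  for (t in ts) {
    active <- A < settings$early_termination_alpha
    if (!any(active)) break
    P <- base + rep(t, npx) %o% geom$basis$w
    inside <- P[, 1] >= 0.5 & P[, 1] <= d[1] + 0.5 &
              P[, 2] >= 0.5 & P[, 2] <= d[2] + 0.5 &
              P[, 3] >= 0.5 & P[, 3] <= d[3] + 0.5
    sel <- which(active & inside)
    if (length(sel) == 0L) next
    Ps <- P[sel, , drop = FALSE]
    I <- trilinear_interp(vol$data, Ps)
    delta <- if (is.null(shift)) 0 else trilinear_interp(shift$delta, Ps)
    rgba <- evaluate_shifted_tf(tf, I, delta, dom)
    aprime <- 1 - (1 - rgba[, 4])^expo
    w <- (1 - A[sel]) * aprime
    C[sel, ] <- C[sel, ] + w * rgba[, 1:3]
    A[sel] <- A[sel] + w
  }
  bg <- settings$background
  C <- C + (1 - A) * bg[4] * rep(bg[1:3], each = npx)
  A <- A + (1 - A) * bg[4]
  img <- array(cbind(C, A), c(W, H, 4L))
  structure(img, class = c("rgba_image", class(img)))
}

#' Write an RGBA image as PNG
#'
#' Image y (camera v) increases upward, so the array is flipped to PNG's
#' top-down row order.
#'
#' @param img an `rgba_image` from [render_volume()].
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  d <- dim(img)
  arr <- aperm(img, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  png::writePNG(pmin(pmax(arr, 0), 1), path)
  invisible(path)
}
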