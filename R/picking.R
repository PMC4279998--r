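#' Pick the 3D voxel under a 2D image click
#'
#' Marches a ray from the clicked pixel along the viewing direction at the
#' renderer's sampling interval, evaluates the opacity of each sample
#' through the shifted transfer function, and accumulates the plain
#' running sum of sample opacities. The returned position is the first
#' sample at which the sum reaches `alpha_th`, rounded to the nearest
#' voxel — a sample close to the front surface of the structure the user
#' clicked. Because the opacities are evaluated through the shifted
#' transfer function, structures made visible only by an applied edit are
#' pickable, which is what lets picked positions feed back into further
#' edits.
#'
#' @param vol a [scalar_volume()].
#' @param tf a [transfer_function()].
#' @param shift optional `shift_field` on the same grid.
#' @param settings a [render_settings()]; geometry and step must match the
#'   render the click was made on.
#' @param x_click `c(i, j)` pixel coordinates in the rendered image.
#' @param alpha_th opacity-sum threshold in (0, 1]; default 0.3.
#' @return An object of class `pick_result` with `position` (integer
#'   voxel coordinates, `NA` on a miss), `accumulated_opacity`,
#'   `threshold`, and `hit`.
#' @export
pick_voxel <- function(vol, tf, shift = NULL, settings = render_settings(),
                       x_click, alpha_th = 0.3) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(tf, "transfer_function"),
            inherits(settings, "render_settings"))
  if (!is.numeric(alpha_th) || alpha_th <= 0 || alpha_th > 1)
    stop("`alpha_th` must be in (0, 1]")
  d <- dim(vol$data)
  if (!is.null(shift) && !identical(dim(shift$delta), d))
    stop("shift field grid does not match the volume")
  geom <- ray_geometry(d, settings)
  if (x_click[1] < 1 || x_click[1] > geom$width ||
      x_click[2] < 1 || x_click[2] > geom$height)
    stop("`x_click` outside the image bounds")
  s <- pixel_plane_coords(geom, x_click[1], x_click[2])
  ts <- seq(geom$rt[1] + settings$step / 2, geom$rt[2], by = settings$step)
  P <- s[1] * matrix(geom$basis$u, length(ts), 3L, byrow = TRUE) +
       s[2] * matrix(geom$basis$v, length(ts), 3L, byrow = TRUE) +
       ts * matrix(geom$basis$w, length(ts), 3L, byrow = TRUE)
  inside <- P[, 1] >= 0.5 & P[, 1] <= d[1] + 0.5 &
            P[, 2] >= 0.5 & P[, 2] <= d[2] + 0.5 &
            P[, 3] >= 0.5 & P[, 3] <= d[3] + 0.5
  alpha <- numeric(length(ts))
  if (any(inside)) {
    Ps <- P[inside, , drop = FALSE]
    I <- trilinear_interp(vol$data, Ps)
    delta <- if (is.null(shift)) 0 else trilinear_interp(shift$delta, Ps)
    alpha[inside] <- evaluate_shifted_tf(tf, I, delta, vol$intensity_domain)[, 4]
  }
  acc <- cumsum(alpha)
  hit_i <- which(acc >= alpha_th)[1]
  if (is.na(hit_i)) {
    res <- list(position = rep(NA_integer_, 3L),
                accumulated_opacity = if (length(acc)) acc[length(acc)] else 0,
                threshold = alpha_th, hit = FALSE)
  } else {
    pos <- pmin(pmax(round(P[hit_i, ]), 1L), d)
    res <- list(position = as.integer(pos),
                accumulated_opacity = acc[hit_i],
                threshold = alpha_th, hit = TRUE)
  }
  structure(res, class = "pick_result")
}

#' @export
print.pick_result <- function(x, ...) {
  if (x$hit)
    cat(sprintf("pick_result: hit at (%d, %d, %d), sum(alpha) = %.3f (threshold %.3f)\n",
                x$position[1], x$position[2], x$position[3],
                x$accumulated_opacity, x$threshold))
  else
    cat(sprintf("pick_result: miss (sum(alpha) = %.3f < %.3f)\n",
                x$accumulated_opacity, x$threshold))
  invisible(x)
}
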