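# Shared fixtures, built in code at test time.

# Opacity ramp used across rendering tests: transparent below 0.3,
# partially opaque from 0.45 up. Makes full-intensity tubes (0.9) and
# mid-intensity tubes (0.45) visible while the vessel-shadowed portion
# (0.45 * 0.4 = 0.18) stays invisible until an edit shifts it.
ramp_preset <- function() {
  transfer_function(data.frame(
    intensity = c(0, 0.3, 0.45, 1),
    r = c(1, 1, 1, 1), g = c(0.9, 0.9, 0.9, 0.9), b = c(0.6, 0.6, 0.6, 0.6),
    a = c(0, 0, 0.6, 0.85)))
}

# Fully binary preset: opaque white above `cut`, transparent below.
step_preset <- function(cut = 0.5) {
  transfer_function(data.frame(
    intensity = c(0, cut - 1e-6, cut, 1),
    r = 1, g = 1, b = 1,
    a = c(0, 0, 1, 1)))
}

# Small deterministic volume with a broad spread of intensities.
wavy_volume <- function(n = 16) {
  g <- seq_len(n)
  a <- outer(outer(sin(g / 2), cos(g / 3)), sin(g / 5 + 1))
  scalar_volume((a - min(a)) / (max(a) - min(a)))
}

# The default study scene (96^3 crossing-tube phantom) plus preprocessed
# volume and features, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

get_scene96 <- function() {
  if (is.null(.fixture_cache$scene96)) {
    scene <- make_crossing_scene(seed = 42)
    vol <- normalize_intensity(median_filter(scene$volume))
    fv <- build_feature_volume(vol)
    .fixture_cache$scene96 <- list(scene = scene, vol = vol, fv = fv)
  }
  .fixture_cache$scene96
}

# First axis voxel of a given structure that lies outside (or inside) the
# shadow box.
axis_voxel_where <- function(scene, id, in_shadow = FALSE, tol = 0.5) {
  av <- axis_voxels(scene, id, tol = tol)
  if (nrow(av) == 0) return(NULL)
  inside <- scene$shadow_mask[av]
  sel <- if (in_shadow) which(inside) else which(!inside)
  if (length(sel) == 0) return(NULL)
  av[sel[ceiling(length(sel) / 2)], ]
}

# Independent scalar evaluation of the shift formula at one voxel:
# Delta = (I0 - I) * exp(-alpha * dF) / (1 + exp(dE - beta)).
# All feature lookups and distances are recomputed with plain scalar
# arithmetic from the raw feature arrays.
brute_shift_at <- function(vol, fv, edit, i, j, k) {
  d <- dim(vol$data)
  i0 <- round(edit$x0)
  I0 <- vol$data[i0[1], i0[2], i0[3]]
  e_ref <- fv$e3[i0[1], i0[2], i0[3], ]
  lr_ref <- fv$lambda_ratio[i0[1], i0[2], i0[3]]
  lin <- function(p) p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
  c_ref <- fv$channels[lin(i0), ]
  dF <- switch(edit$metric,
    orientation = {
      e <- fv$e3[i, j, k, ]
      1 - abs(sum(e * e_ref))
    },
    lambda_ratio = abs(fv$lambda_ratio[i, j, k] - lr_ref) / fv$sigma_lambda,
    mahalanobis = {
      dv <- fv$channels[lin(c(i, j, k)), ] - c_ref
      sqrt(drop(t(dv) %*% solve(fv$covariance) %*% dv))
    },
    dot = {
      cx <- fv$channels[lin(c(i, j, k)), ]
      c0 <- c_ref
      if (sum(cx^2) > 0) cx <- cx / sqrt(sum(cx^2))
      if (sum(c0^2) > 0) c0 <- c0 / sqrt(sum(c0^2))
      1 - sum(cx * c0)
    })
  s <- vol$spacing / vol$spacing[1]
  dE <- Inf
  for (m in seq_len(nrow(edit$stroke_centers))) {
    cc <- edit$stroke_centers[m, ]
    dE <- min(dE, sqrt(sum((((c(i, j, k)) - cc) * s)^2)))
  }
  (I0 - vol$data[i, j, k]) * exp(-edit$alpha * dF) / (1 + exp(dE - edit$beta))
}
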