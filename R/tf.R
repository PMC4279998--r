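#' Construct a 1D RGBA transfer function
#'
#' A piecewise-linear map from intensity to RGBA, defined by ordered
#' control points. This is the "preset" that all localized edits shift
#' into: an edit never modifies the preset, it offsets the intensity that
#' is looked up in it.
#'
#' @param control_points data.frame with columns `intensity`, `r`, `g`,
#'   `b`, `a`; intensities strictly increasing, at least 2 rows, all RGBA
#'   components in \[0, 1\].
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(control_points) {
  cp <- as.data.frame(control_points)
  need <- c("intensity", "r", "g", "b", "a")
  if (!all(need %in% names(cp)))
    stop("control points need columns: ", paste(need, collapse = ", "))
  cp <- cp[need]
  if (nrow(cp) < 2L) stop("at least 2 control points required")
  if (any(diff(cp$intensity) <= 0))
    stop("control-point intensities must be strictly increasing")
  rgba <- as.matrix(cp[c("r", "g", "b", "a")])
  if (any(!is.finite(as.matrix(cp))) || any(rgba < 0) || any(rgba > 1))
    stop("RGBA components must be finite and in [0, 1]")
  structure(list(control_points = cp), class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("transfer_function: %d control points on [%g, %g]\n",
              nrow(x$control_points),
              min(x$control_points$intensity), max(x$control_points$intensity)))
  invisible(x)
}

#' Evaluate a transfer function
#'
#' Piecewise-linear interpolation between control points; queries outside
#' the control-point range clamp to the nearest endpoint.
#'
#' @param tf a [transfer_function()].
#' @param intensity numeric vector of intensities.
#' @return Numeric matrix `length(intensity)` x 4, columns `r, g, b, a`,
#'   all values in \[0, 1\].
#' @export
tf_evaluate <- function(tf, intensity) {
  stopifnot(inherits(tf, "transfer_function"))
  cp <- tf$control_points
  out <- matrix(0, length(intensity), 4L,
                dimnames = list(NULL, c("r", "g", "b", "a")))
  for (j in 1:4)
    out[, j] <- approx(cp$intensity, cp[[j + 1L]], xout = intensity,
                       rule = 2)$y
  out
}

#' Evaluate the shifted transfer function
#'
#' The core lookup of the method: `TF_preset(I(x) + Delta(x))`, with the
#' shifted intensity clamped to the intensity domain. A zero shift reduces
#' exactly to the preset.
#'
#' @param tf a [transfer_function()].
#' @param intensity numeric vector of voxel/sample intensities.
#' @param delta numeric shift values (same length as `intensity`, or a
#'   scalar).
#' @param intensity_domain numeric length-2 clamp range (default `c(0, 1)`,
#'   the normalized domain).
#' @return RGBA matrix as in [tf_evaluate()].
#' @export
evaluate_shifted_tf <- function(tf, intensity, delta = 0,
                                intensity_domain = c(0, 1)) {
  x <- pmin(pmax(intensity + delta, intensity_domain[1]), intensity_domain[2])
  tf_evaluate(tf, x)
}

#' Read a transfer-function preset from JSON
#'
#' The preset format is a JSON list of control points:
#' `[{"intensity": t, "rgba": [r, g, b, a]}, ...]`.
#'
#' @param path JSON file path.
#' @return A [transfer_function()].
#' @export
read_tf_preset <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  cp <- do.call(rbind, lapply(raw, function(p) {
    data.frame(intensity = p$intensity, r = p$rgba[1], g = p$rgba[2],
               b = p$rgba[3], a = p$rgba[4])
  }))
  transfer_function(cp)
}

#' Write a transfer-function preset to JSON
#'
#' @param tf a [transfer_function()].
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_tf_preset <- function(tf, path) {
  stopifnot(inherits(tf, "transfer_function"))
  cp <- tf$control_points
  pts <- lapply(seq_len(nrow(cp)), function(i) {
    list(intensity = cp$intensity[i],
         rgba = c(cp$r[i], cp$g[i], cp$b[i], cp$a[i]))
  })
  jsonlite::write_json(pts, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
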