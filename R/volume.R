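#' Construct a 3D scalar volume
#'
#' A `scalar_volume` holds the intensity field I(x) on a regular grid with
#' per-axis physical spacing. Voxels are indexed `[x, y, z]`, 1-based; the
#' world position of voxel (i, j, k) is `(i-1, j-1, k-1) * spacing` in
#' micrometres.
#'
#' @param data numeric 3D array, indexed `[x, y, z]`.
#' @param spacing numeric length-3, per-axis step in micrometres; all > 0.
#' @param intensity_domain numeric length-2 `(I_min, I_max)` of the
#'   representable range. Defaults to `c(0, 1)` when all data lie inside
#'   it, otherwise to `range(data)`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), intensity_domain = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (got ", length(dim(data)), " dims)")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  if (is.null(intensity_domain)) {
    rng <- range(data)
    intensity_domain <- if (rng[1] >= 0 && rng[2] <= 1) c(0, 1) else rng
  }
  intensity_domain <- as.numeric(intensity_domain)
  if (length(intensity_domain) != 2L || intensity_domain[1] >= intensity_domain[2])
    stop("`intensity_domain` must be (min, max) with min < max")
  if (min(data) < intensity_domain[1] || max(data) > intensity_domain[2])
    stop("data fall outside `intensity_domain`")
  structure(
    list(data = data, spacing = spacing, intensity_domain = intensity_domain),
    class = "scalar_volume"
  )
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "scalar_volume: %d x %d x %d voxels, spacing (%g, %g, %g) um, domain [%g, %g]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$intensity_domain[1], x$intensity_domain[2]))
  invisible(x)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = "tiff",
    nrrd = "nrrd",
    stop("cannot infer volume format from extension '.", ext,
         "'; pass `format` explicitly"))
}

#' Read a 3D volume from disk
#'
#' Supports multi-page grayscale TIFF stacks (page axis = z) and raw-encoded
#' NRRD. TIFF carries no 3D spacing metadata, so `spacing` should be passed
#' explicitly; when absent it defaults to (1, 1, 1) um with a warning. NRRD
#' spacing is taken from the `spacings` header field.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tiff"` or `"nrrd"`.
#' @param spacing optional per-axis spacing in um, overriding file metadata.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nrrd"), spacing = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("TIFF pages must be single-channel 2D (grayscale); got multi-channel data")
    nz <- length(pages)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    arr <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
    if (is.null(spacing)) {
      warning("TIFF has no spacing metadata; defaulting to (1, 1, 1) um")
      spacing <- c(1, 1, 1)
    }
    scalar_volume(arr, spacing = spacing)
  } else {
    nr <- read_nrrd(path)
    if (length(dim(nr$data)) != 3L)
      stop("NRRD is not 3D (dimension = ", length(dim(nr$data)), ")")
    if (is.null(spacing)) {
      spacing <- nr$spacings
      if (is.null(spacing)) {
        warning("NRRD has no spacings field; defaulting to (1, 1, 1) um")
        spacing <- c(1, 1, 1)
      }
    }
    scalar_volume(nr$data, spacing = spacing)
  }
}

#' Write a 3D volume to disk
#'
#' TIFF stacks are written as 32-bit float pages (z = page axis); NRRD as
#' raw little-endian doubles with the spacing recorded in the header, so
#' NRRD round-trips are exact. Shift fields can be persisted the same way
#' as image volumes.
#'
#' @param vol a [scalar_volume()], or a `shift_field` (its delta grid is
#'   written).
#' @param path destination path.
#' @param format `"auto"`, `"tiff"` or `"nrrd"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (inherits(vol, "shift_field"))
    vol <- scalar_volume(vol$delta, spacing = vol$spacing,
                         intensity_domain = range(vol$delta) + c(-1, 1))
  stopifnot(inherits(vol, "scalar_volume"))
  if (format == "tiff") {
    d <- dim(vol$data)
    rng <- vol$intensity_domain
    if (min(vol$data) < 0 || max(vol$data) > 1)
      stop("TIFF output requires data in [0, 1]; normalize first or use NRRD")
    pages <- lapply(seq_len(d[3]), function(k) t(vol$data[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    write_nrrd(vol$data, path, spacings = vol$spacing)
  }
  invisible(path)
}

#' 3D median filter
#'
#' Replaces every voxel by the median of its cubic `(2*radius+1)^3`
#' neighborhood with replicate edge handling; the standard denoising
#' preprocessing step before feature extraction. `radius = 0` is the
#' identity.
#'
#' @param vol a [scalar_volume()].
#' @param radius non-negative integer window radius in voxels (default 1,
#'   a 3x3x3 kernel).
#' @return A filtered [scalar_volume()].
#' @export
median_filter <- function(vol, radius = 1L) {
  stopifnot(inherits(vol, "scalar_volume"))
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 0L)
    stop("`radius` must be a non-negative integer")
  if (radius == 0L) return(vol)
  d <- dim(vol$data)
  out <- median_filter_cpp(as.vector(vol$data), as.integer(d), radius)
  scalar_volume(array(out, d), spacing = vol$spacing,
                intensity_domain = vol$intensity_domain)
}

#' Rescale intensities to [0, 1]
#'
#' Affine rescale of the data range to exactly [0, 1] and reset of the
#' intensity domain to (0, 1). All feature and shift computation assumes a
#' normalized volume so that transfer-function domains and shift magnitudes
#' are comparable across inputs.
#'
#' @param vol a [scalar_volume()].
#' @return A normalized [scalar_volume()] with `intensity_domain = c(0, 1)`.
#' @export
normalize_intensity <- function(vol) {
  stopifnot(inherits(vol, "scalar_volume"))
  rng <- range(vol$data)
  if (rng[1] >= rng[2])
    stop("degenerate input: constant volume cannot be normalized")
  out <- (vol$data - rng[1]) / (rng[2] - rng[1])
  scalar_volume(out, spacing = vol$spacing, intensity_domain = c(0, 1))
}
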