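#' Phase image (optical-thickness map)
#'
#' Container for a 2-D map of optical thickness, the phase shift of light
#' through the sample expressed in length units (phase as a fraction of a
#' wavelength, times the wavelength). Optical thickness of a uniform object
#' equals its physical thickness times the refractive-index difference to the
#' surrounding medium, so all downstream quantities (optical volume, dry
#' mass) are integrals of this map.
#'
#' @param optical_thickness Numeric matrix, optical thickness in um per
#'   pixel. Must be finite everywhere.
#' @param pixel_size Pixel edge length in um (square pixels). Must be > 0.
#' @param wavelength Illumination wavelength in metres; metadata carried
#'   along for provenance (the map itself is already in length units).
#'   Default 624e-9 m (red LED array).
#' @return An object of class `phase_image` with fields
#'   `optical_thickness`, `pixel_size`, `wavelength`.
#' @export
phase_image <- function(optical_thickness, pixel_size, wavelength = 624e-9) {
  if (!is.matrix(optical_thickness) || !is.numeric(optical_thickness))
    stop("optical_thickness must be a numeric matrix")
  if (!all(is.finite(optical_thickness)))
    stop("optical_thickness must be finite everywhere")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/pixel)")
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0)
    stop("wavelength must be a single positive number (m)")
  structure(
    list(optical_thickness = optical_thickness,
         pixel_size = as.numeric(pixel_size),
         wavelength = as.numeric(wavelength)),
    class = "phase_image")
}

#' @export
print.phase_image <- function(x, ...) {
  d <- dim(x$optical_thickness)
  cat(sprintf("phase_image: %d x %d px, %.4g um/px, range [%.4g, %.4g] um\n",
              d[1], d[2], x$pixel_size,
              min(x$optical_thickness), max(x$optical_thickness)))
  invisible(x)
}

#' @export
dim.phase_image <- function(x) dim(x$optical_thickness)

# Resolve a region specification against an image-sized matrix.
# Accepted forms: a logical matrix of the image shape, or a two-column
# integer matrix / data.frame of 0-based (row, col) pixel coordinates.
# Returns a logical matrix.
resolve_region <- function(region, dims) {
  if (is.logical(region) && is.matrix(region)) {
    if (!identical(dim(region), as.integer(dims)))
      stop("logical region must have the same shape as the image")
    return(region)
  }
  if (is.data.frame(region)) region <- as.matrix(region[, 1:2])
  if (is.matrix(region) && is.numeric(region) && ncol(region) == 2L) {
    r <- region[, 1] + 1L
    c <- region[, 2] + 1L
    if (any(r < 1 | r > dims[1] | c < 1 | c > dims[2]))
      stop("region contains pixels outside the image")
    m <- matrix(FALSE, dims[1], dims[2])
    m[cbind(r, c)] <- TRUE
    return(m)
  }
  stop("region must be a logical matrix or a 2-column (row, col) coordinate set")
}

#' Subtract the mean background level from a phase image
#'
#' Removes the additive phase offset by subtracting the mean optical
#' thickness over a user-chosen background region containing no traps or
#' cells. Only the mean is removed (no plane or surface fit), so object
#' contrast is preserved exactly.
#'
#' @param phase A [phase_image].
#' @param background_region Region specification: logical matrix of the
#'   image shape, or 2-column 0-based (row, col) coordinates. Must be
#'   non-empty and should be disjoint from all trap tiles.
#' @return A [phase_image] whose mean over `background_region` is 0.
#' @export
background_correct <- function(phase, background_region) {
  stopifnot(inherits(phase, "phase_image"))
  reg <- resolve_region(background_region, dim(phase$optical_thickness))
  if (!any(reg)) stop("background_region is empty")
  mu <- mean(phase$optical_thickness[reg])
  phase$optical_thickness <- phase$optical_thickness - mu
  phase
}

#' Optical volume of a region
#'
#' Integrates optical thickness over a pixel region: the discrete form of
#' the area integral of phase (as a fraction of wavelength) times
#' wavelength, i.e. sum of per-pixel optical thickness times pixel area.
#' Units: um^3.
#'
#' @param phase A [phase_image].
#' @param region Region specification (see [background_correct()]); must be
#'   non-empty and inside the image.
#' @return Optical volume in um^3 (scalar).
#' @export
optical_volume <- function(phase, region) {
  stopifnot(inherits(phase, "phase_image"))
  reg <- resolve_region(region, dim(phase$optical_thickness))
  if (!any(reg)) stop("region is empty")
  sum(phase$optical_thickness[reg]) * phase$pixel_size^2
}
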