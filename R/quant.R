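#' Material / medium optics
#'
#' Refractive indices of the microfabricated trap material and the aqueous
#' medium filling the channel. The index difference `delta_n` drives every
#' optical-thickness signal from the device structures; index matching
#' (`delta_n -> 0`) is what keeps trap phase shifts below a wavelength.
#'
#' @param n_material Refractive index of the polymer (e.g. 1.3541 for a
#'   fluorinated low-index polymer, ~1.43 for PDMS).
#' @param n_medium Refractive index of the solution, default 1.330 (water).
#' @return Object of class `material_optics` with `n_material`, `n_medium`,
#'   `delta_n`.
#' @export
material_optics <- function(n_material = 1.3541, n_medium = 1.330) {
  if (n_material <= 1 || n_material >= 2 || n_medium <= 1 || n_medium >= 2)
    stop("refractive indices must lie in (1, 2)")
  structure(list(n_material = n_material, n_medium = n_medium,
                 delta_n = n_material - n_medium),
            class = "material_optics")
}

#' Trap geometry
#'
#' Each hydrodynamic trap consists of `cylinders_per_trap` identical
#' vertical cylinders (circular cross-section) spanning the channel height.
#'
#' @param radius Cylinder radius in um (> 0), default 7.5.
#' @param height Trap/channel height in um (> 0), default 9.8.
#' @param cylinders_per_trap Integer >= 1, default 2 (a pair with a small
#'   gap that funnels cells into the trap).
#' @return Object of class `trap_geometry`.
#' @export
trap_geometry <- function(radius = 7.5, height = 9.8, cylinders_per_trap = 2L) {
  if (radius <= 0 || height <= 0) stop("radius and height must be positive")
  cylinders_per_trap <- as.integer(cylinders_per_trap)
  if (cylinders_per_trap < 1L) stop("cylinders_per_trap must be >= 1")
  structure(list(radius = radius, height = height,
                 cylinders_per_trap = cylinders_per_trap),
            class = "trap_geometry")
}

#' Mass calibration: specific refractive increment
#'
#' The specific refractive increment `alpha` (dn/dc of biomolecules in
#' solution) converts integrated optical volume to dry mass. With optical
#' volume in um^3 and mass in pg, the default alpha = 1.8e-4 m^3/kg equals
#' exactly 0.18 um^3/pg.
#'
#' @param alpha Specific refractive increment in m^3/kg (> 0), default
#'   1.8e-4.
#' @param wavelength Illumination wavelength in metres, default 624e-9.
#' @return Object of class `mass_calibration` with `alpha` (m^3/kg),
#'   `alpha_um3_per_pg` and `wavelength`.
#' @export
mass_calibration <- function(alpha = 1.8e-4, wavelength = 624e-9) {
  if (alpha <= 0) stop("alpha must be positive")
  # 1 m^3/kg = 1e18 um^3 / 1e15 pg = 1e3 um^3/pg
  structure(list(alpha = alpha, alpha_um3_per_pg = alpha * 1e3,
                 wavelength = wavelength),
            class = "mass_calibration")
}

#' Theoretical optical volume of a trap
#'
#' For cylinders of radius `r` and height `h` made of material with index
#' difference `delta_n` to the medium, each cylinder contributes optical
#' volume `pi r^2 h delta_n`; a trap of several cylinders is their sum.
#'
#' @param geom A [trap_geometry].
#' @param optics A [material_optics].
#' @return Optical volume in um^3.
#' @export
theoretical_trap_volume <- function(geom, optics) {
  stopifnot(inherits(geom, "trap_geometry"), inherits(optics, "material_optics"))
  geom$cylinders_per_trap * pi * geom$radius^2 * geom$height * optics$delta_n
}

#' Refractive-index difference from a phase measurement
#'
#' For a uniform slab of known thickness (e.g. the water-filled channel of
#' known height against the bulk polymer), the index difference is the mean
#' optical thickness divided by the physical thickness.
#'
#' @param phase A [phase_image] (optical thickness of the uniform region,
#'   um).
#' @param channel_region Region specification over uniform-thickness
#'   material.
#' @param height Physical thickness in um (> 0).
#' @return `delta_n` (dimensionless).
#' @export
delta_n_from_phase <- function(phase, channel_region, height) {
  stopifnot(inherits(phase, "phase_image"))
  if (!is.numeric(height) || length(height) != 1L || height <= 0)
    stop("height must be a single positive number (um)")
  reg <- resolve_region(channel_region, dim(phase$optical_thickness))
  if (!any(reg)) stop("channel_region is empty")
  mean(phase$optical_thickness[reg]) / height
}

#' Absolute refractive index from an index difference
#'
#' @param delta_n Measured refractive-index difference.
#' @param n_medium Refractive index of the reference medium (default 1.330,
#'   water).
#' @return `n_medium + delta_n`.
#' @export
refractive_index <- function(delta_n, n_medium = 1.330) {
  n_medium + delta_n
}

#' Convert optical volume to dry mass
#'
#' `mass = optical_volume / alpha`, with alpha expressed in um^3/pg so the
#' unit conversion is exact (default 0.18 um^3/pg).
#'
#' @param v Optical volume in um^3 (scalar or vector).
#' @param cal A [mass_calibration].
#' @return Mass in pg.
#' @export
mass_from_optical_volume <- function(v, cal = mass_calibration()) {
  stopifnot(inherits(cal, "mass_calibration"))
  v / cal$alpha_um3_per_pg
}

# Robust occupancy rule: a trap is empty iff its volume lies within
# median +/- 3 * IQR of the lower half of volumes. Cells only add volume,
# so the lower half estimates the empty-trap spread even when a sizeable
# fraction of traps hold cells.
classify_occupancy <- function(volumes) {
  med <- stats::median(volumes)
  lower <- volumes[volumes <= med]
  iqr_low <- stats::IQR(lower, type = 7)
  tol <- 3 * iqr_low + 1e-8 * (abs(med) + 1)
  abs(volumes - med) > tol
}

#' Measure per-trap optical volumes and cell masses in one frame
#'
#' Integrates optical volume over each trap tile, identifies empty traps,
#' subtracts the mean empty-trap optical volume (the reference `R`) from
#' occupied traps, and converts the excess to cell dry mass. Because the
#' mask is static and the reference is measured from the same frame, no
#' cell segmentation or tracking is involved.
#'
#' @param phase A background-corrected [phase_image].
#' @param mask A [trap_mask].
#' @param empty_ids Optional integer vector of trap ids known to be empty;
#'   all other traps are treated as occupied. If `NULL` (default), occupancy
#'   is auto-classified: empty iff the trap volume lies within
#'   median +/- 3x the IQR of the lower half of trap volumes.
#' @param cal A [mass_calibration].
#' @param frame Frame index recorded in the output (default 1).
#' @return A data frame (`frame`, `trap_id`, `optical_volume_um3`,
#'   `occupied`, `cell_optical_volume_um3`, `cell_mass_pg`); the cell
#'   columns are `NA` for empty traps.
#' @export
measure_traps <- function(phase, mask, empty_ids = NULL,
                          cal = mass_calibration(), frame = 1L) {
  stopifnot(inherits(phase, "phase_image"), inherits(mask, "trap_mask"))
  if (!identical(dim(mask$labels), dim(phase$optical_thickness)))
    stop("mask and phase image shapes differ")
  ids <- mask$centers$trap_id
  px2 <- phase$pixel_size^2
  sums <- rowsum(as.vector(phase$optical_thickness)[mask$labels != 0L],
                 as.vector(mask$labels)[mask$labels != 0L])
  vol <- as.numeric(sums[match(as.character(ids), rownames(sums)), 1]) * px2

  if (is.null(empty_ids)) {
    occupied <- classify_occupancy(vol)
    if (all(occupied))
      stop("auto-classification found no empty traps")
  } else {
    occupied <- !(ids %in% empty_ids)
  }
  n_empty <- sum(!occupied)
  if (n_empty < 3L)
    stop(sprintf("need at least 3 empty traps for the reference (found %d)",
                 n_empty))
  ref <- mean(vol[!occupied])
  cell_v <- ifelse(occupied, vol - ref, NA_real_)
  data.frame(frame = as.integer(frame), trap_id = ids,
             optical_volume_um3 = vol, occupied = occupied,
             cell_optical_volume_um3 = cell_v,
             cell_mass_pg = mass_from_optical_volume(cell_v, cal))
}

#' Measure a sequence of frames against one static mask
#'
#' @param phases List of background-corrected [phase_image]s.
#' @param mask A [trap_mask].
#' @param empty_ids,cal Passed to [measure_traps()].
#' @return Row-bound measurement table with a `frame` column.
#' @export
measure_stack <- function(phases, mask, empty_ids = NULL,
                          cal = mass_calibration()) {
  do.call(rbind, lapply(seq_along(phases), function(f)
    measure_traps(phases[[f]], mask, empty_ids = empty_ids, cal = cal,
                  frame = f)))
}
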