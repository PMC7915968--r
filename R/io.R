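# On-disk image format: multi-page 32-bit TIFF plus a JSON sidecar
# (<file>.json). TIFF samples hold each page affinely rescaled to [0, 1];
# the sidecar records the per-page (min, max) range and the acquisition
# metadata (pixel size, wavelength), so real values round-trip to ~1e-9
# relative precision. All writers in the package use this convention.

write_image_stack <- function(mats, path, meta = list()) {
  lo <- vapply(mats, min, numeric(1))
  hi <- vapply(mats, max, numeric(1))
  enc <- lapply(seq_along(mats), function(i) {
    rng <- hi[i] - lo[i]
    if (rng == 0) matrix(0, nrow(mats[[i]]), ncol(mats[[i]]))
    else (mats[[i]] - lo[i]) / rng
  })
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, compression = "LZW")
  side <- c(list(pages = length(mats), min = lo, max = hi), meta)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_image_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  mats <- lapply(seq_along(pages), function(i) {
    rng <- side$max[i] - side$min[i]
    pages[[i]] * rng + side$min[i]
  })
  list(mats = mats, meta = side)
}

#' Write phase images to a multi-page 32-bit TIFF stack
#'
#' One page per frame; each page is rescaled to the unit interval and the
#' per-page range, pixel size and wavelength are stored in a JSON sidecar
#' (`<path>.json`) so that [read_phase_stack()] restores physical um
#' values.
#'
#' @param phases A [phase_image] or list of them (common pixel size).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phase_stack <- function(phases, path) {
  if (inherits(phases, "phase_image")) phases <- list(phases)
  stopifnot(all(vapply(phases, inherits, logical(1), "phase_image")))
  write_image_stack(lapply(phases, `[[`, "optical_thickness"), path,
                    meta = list(kind = "phase",
                                pixel_size_um = phases[[1]]$pixel_size,
                                wavelength_m = phases[[1]]$wavelength))
}

#' Read a phase stack written by [write_phase_stack()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return List of [phase_image]s.
#' @export
read_phase_stack <- function(path) {
  s <- read_image_stack(path)
  lapply(s$mats, phase_image, pixel_size = s$meta$pixel_size_um,
         wavelength = s$meta$wavelength_m)
}

#' Write DPC intensity pairs as a multi-page TIFF stack
#'
#' Page order is `[frame][axis][half]`: for each frame, horizontal A,
#' horizontal B, vertical A, vertical B (4 pages per frame).
#'
#' @param pair_frames List of frames; each frame is a list with elements
#'   `horizontal` and `vertical`, both [dpc_image_pair]s (as returned by
#'   [forward_dpc_pairs()]).
#' @param path Output TIFF path.
#' @param pixel_size,wavelength Acquisition metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_dpc_stack <- function(pair_frames, path, pixel_size, wavelength = 624e-9) {
  mats <- list()
  for (fr in pair_frames) {
    stopifnot(inherits(fr$horizontal, "dpc_image_pair"),
              inherits(fr$vertical, "dpc_image_pair"))
    mats <- c(mats, list(fr$horizontal$intensity_a, fr$horizontal$intensity_b,
                         fr$vertical$intensity_a, fr$vertical$intensity_b))
  }
  write_image_stack(mats, path,
                    meta = list(kind = "dpc", frames = length(pair_frames),
                                page_order = "[frame][axis][half]",
                                pixel_size_um = pixel_size,
                                wavelength_m = wavelength))
}

#' Read a DPC stack written by [write_dpc_stack()]
#'
#' @param path TIFF path.
#' @return List with `frames` (list of `horizontal` / `vertical`
#'   [dpc_image_pair]s per frame), `pixel_size_um`, `wavelength_m`.
#' @export
read_dpc_stack <- function(path) {
  s <- read_image_stack(path)
  n <- length(s$mats) / 4L
  if (n != round(n)) stop("DPC stack page count is not a multiple of 4")
  frames <- lapply(seq_len(n), function(f) {
    b <- (f - 1L) * 4L
    list(horizontal = dpc_image_pair(s$mats[[b + 1L]], s$mats[[b + 2L]],
                                     "horizontal"),
         vertical = dpc_image_pair(s$mats[[b + 3L]], s$mats[[b + 4L]],
                                   "vertical"))
  })
  list(frames = frames, pixel_size_um = s$meta$pixel_size_um,
       wavelength_m = s$meta$wavelength_m)
}

#' Export a trap mask as a 16-bit label TIFF and centers CSV
#'
#' Labels are stored as 16-bit integers (0 = background); centers go to
#' `<path>.centers.csv` with columns `trap_id`, `row`, `col` (0-based
#' pixels).
#'
#' @param mask A [trap_mask].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "trap_mask"))
  if (max(mask$labels) > 65535L) stop("more than 65535 traps")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "LZW")
  utils::write.csv(mask$centers[, c("trap_id", "row", "col")],
                   paste0(path, ".centers.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a label TIFF written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write a trap measurement table as CSV
#'
#' Header: `frame,trap_id,optical_volume_um3,occupied,`
#' `cell_optical_volume_um3,cell_mass_pg`; '.' decimal, UTF-8.
#'
#' @param table Measurement table from [measure_traps()] /
#'   [measure_stack()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a measurement table CSV
#'
#' @param path CSV path.
#' @return Measurement table data frame.
#' @export
read_measurements_csv <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  d$occupied <- as.logical(d$occupied)
  d
}

# --- run configuration ----------------------------------------------------

run_config_schema <- function() {
  list(
    paths = list(input = "character", output_dir = "character"),
    acquisition = list(pixel_size_um = "numeric", wavelength_m = "numeric",
                       channel_height_um = "numeric"),
    lattice = list(anchor1 = "numeric2", anchor2 = "numeric2",
                   anchor3 = "numeric2", counts_u = "numeric",
                   counts_v = "numeric", tile_half_diagonals = "numeric2?"),
    optics = list(n_material = "numeric?", n_medium = "numeric?"),
    geometry = list(radius_um = "numeric?", height_um = "numeric?",
                    cylinders_per_trap = "numeric?"),
    calibration = list(alpha_m3_per_kg = "numeric?"),
    stats = list(dt_min = "numeric?", empty_ids = "numericN?"),
    seed = "numeric?")
}

check_block <- function(value, schema, path) {
  if (is.list(schema)) {
    if (!is.list(value))
      stop(sprintf("config key '%s' must be a mapping", path))
    unknown <- setdiff(names(value), names(schema))
    if (length(unknown) > 0)
      stop(sprintf("unknown config key '%s.%s'", path, unknown[1]))
    for (k in names(schema)) {
      spec <- schema[[k]]
      kp <- if (path == "") k else paste0(path, ".", k)
      if (is.null(value[[k]])) {
        req <- is.character(spec) && !grepl("\\?$", spec)
        if (req) stop(sprintf("missing required config key '%s'", kp))
        next
      }
      check_block(value[[k]], spec, kp)
    }
    return(invisible(TRUE))
  }
  type <- sub("\\?$", "", schema)
  v <- value
  ok <- switch(type,
               character = is.character(v) && length(v) == 1L,
               numeric = is.numeric(v) && length(v) == 1L,
               numeric2 = is.numeric(unlist(v)) && length(unlist(v)) == 2L,
               numericN = is.numeric(unlist(v)),
               FALSE)
  if (!ok)
    stop(sprintf("config key '%s' has the wrong type (expected %s)",
                 path, type))
  invisible(TRUE)
}

#' Read and validate a run configuration YAML
#'
#' Required blocks: `paths` (`input`, `output_dir`), `acquisition`
#' (`pixel_size_um`, `wavelength_m`, `channel_height_um`), `lattice`
#' (`anchor1..3` as `[row, col]`, `counts_u`, `counts_v`, optional
#' `tile_half_diagonals`). Optional blocks `optics`, `geometry`,
#' `calibration`, `stats`, and a top-level `seed`. Unknown keys anywhere
#' are rejected by name; defaults fill the optional blocks.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return Validated config list with defaults applied.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  schema <- run_config_schema()
  required_blocks <- c("paths", "acquisition", "lattice")
  for (b in required_blocks)
    if (is.null(cfg[[b]]))
      stop(sprintf("missing required config key '%s'", b))
  check_block(cfg, schema, "")
  defaults <- list(
    optics = list(n_material = 1.3541, n_medium = 1.330),
    geometry = list(radius_um = 7.5, height_um = 9.8, cylinders_per_trap = 2),
    calibration = list(alpha_m3_per_kg = 1.8e-4),
    stats = list(dt_min = 5),
    seed = 1)
  for (b in names(defaults)) {
    if (is.list(defaults[[b]])) {
      for (k in names(defaults[[b]]))
        if (is.null(cfg[[b]][[k]])) cfg[[b]][[k]] <- defaults[[b]][[k]]
    } else if (is.null(cfg[[b]])) cfg[[b]] <- defaults[[b]]
  }
  cfg
}
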