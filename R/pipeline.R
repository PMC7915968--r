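# Workflow entry points tying the stages together; the command-line script
# in inst/cli/trapmass.R is a thin wrapper over these.

write_provenance <- function(out_dir, step, config) {
  rec <- list(step = step,
              package = "trapmass",
              version = as.character(utils::packageVersion("trapmass")),
              config = config)
  jsonlite::write_json(rec, file.path(out_dir, paste0(step, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

lattice_from_config <- function(cfg) {
  fit_lattice(unlist(cfg$lattice$anchor1), unlist(cfg$lattice$anchor2),
              unlist(cfg$lattice$anchor3),
              cfg$lattice$counts_u, cfg$lattice$counts_v)
}

mask_from_config <- function(cfg, image_shape) {
  lat <- lattice_from_config(cfg)
  thd <- cfg$lattice$tile_half_diagonals
  render_mask(lat, image_shape,
              tile_half_diagonals = if (is.null(thd)) NULL else unlist(thd))
}

#' Run the simulation workflow and write its outputs
#'
#' Renders the synthetic device, writes the phase stack, the DPC image
#' pair stack, the per-frame ground-truth CSV and the resolved
#' configuration (YAML + provenance JSON) to `out_dir`.
#'
#' @param config A [sim_config], or path to a YAML file whose keys are
#'   [sim_config()] arguments.
#' @param out_dir Output directory (created if missing).
#' @param write_dpc Also synthesize and write DPC intensity pairs per
#'   frame (default TRUE).
#' @return Invisibly, a list of the written file paths.
#' @export
run_simulate <- function(config, out_dir, write_dpc = TRUE) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    unknown <- setdiff(names(args), names(formals(sim_config)))
    if (length(unknown) > 0)
      stop(sprintf("unknown simulation config key '%s'", unknown[1]))
    config <- do.call(sim_config, args)
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  phase_path <- file.path(out_dir, "phase.tif")
  dpc_path <- file.path(out_dir, "dpc.tif")

  phases <- vector("list", config$frames)
  sim <- simulate_timelapse(config,
                            frame_callback = function(f, ph) phases[[f]] <<- ph)
  write_phase_stack(phases, phase_path)
  if (write_dpc) {
    pairs <- lapply(seq_len(config$frames), function(f)
      forward_dpc_pairs(phases[[f]], config, seed = config$seed + 100L + f))
    write_dpc_stack(pairs, dpc_path, pixel_size = config$pixel_size,
                    wavelength = config$wavelength)
  }
  truth_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  cfg_list <- unclass(config)
  yaml::write_yaml(cfg_list, file.path(out_dir, "sim_config.yaml"))
  write_provenance(out_dir, "simulate", cfg_list)
  invisible(list(phase = phase_path,
                 dpc = if (write_dpc) dpc_path else NULL,
                 truth = truth_path))
}

#' Reconstruct phase maps from a DPC stack
#'
#' Reads a `[frame][axis][half]`-ordered DPC TIFF stack, forms the
#' normalized DPC signals, integrates them into optical-thickness maps and
#' writes a phase stack. The additive constant of each frame is anchored on
#' the trap-free background defined by the configured lattice mask.
#'
#' @param config Run configuration (path or list, see
#'   [read_run_config()]); `paths$input` must point at the DPC stack.
#' @param gradient_gain,regularization Reconstruction parameters (defaults
#'   1.0 and 1e-4; use 0 regularization for noise-free synthetic data).
#' @return Invisibly, the written phase stack path.
#' @export
run_reconstruct <- function(config, gradient_gain = 1.0, regularization = 1e-4) {
  cfg <- read_run_config(config)
  stack <- read_dpc_stack(cfg$paths$input)
  dir.create(cfg$paths$output_dir, recursive = TRUE, showWarnings = FALSE)
  shape <- dim(stack$frames[[1]]$horizontal$intensity_a)
  mask <- mask_from_config(cfg, shape)
  anchor <- mask$labels == 0L
  params <- recon_params(gradient_gain, regularization, anchor)
  phases <- lapply(stack$frames, function(fr) {
    sx <- compute_dpc_signal(fr$horizontal)
    sy <- compute_dpc_signal(fr$vertical)
    reconstruct_phase(sx, sy, params, pixel_size = cfg$acquisition$pixel_size_um,
                      wavelength = cfg$acquisition$wavelength_m)
  })
  out <- file.path(cfg$paths$output_dir, "phase.tif")
  write_phase_stack(phases, out)
  write_provenance(cfg$paths$output_dir, "reconstruct",
                   c(cfg, list(gradient_gain = gradient_gain,
                               regularization = regularization)))
  invisible(out)
}

#' Measure trap optical volumes and cell masses from a phase stack
#'
#' For each frame: background-correct on the trap-free region of the
#' lattice mask, integrate per-trap optical volume, classify occupancy,
#' subtract the mean empty-trap reference and convert to cell mass. Writes
#' `measurements.csv`, `summary.csv` (statistic, value, units, n) and a
#' provenance record to the configured output directory.
#'
#' @param config Run configuration (path or list); `paths$input` must
#'   point at a phase stack written by [write_phase_stack()].
#' @return Invisibly, the measurement table.
#' @export
run_measure <- function(config) {
  cfg <- read_run_config(config)
  if (!file.exists(cfg$paths$input))
    stop(sprintf("input '%s' does not exist", cfg$paths$input))
  phases <- read_phase_stack(cfg$paths$input)
  dir.create(cfg$paths$output_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- mask_from_config(cfg, dim(phases[[1]]$optical_thickness))
  background <- mask$labels == 0L
  cal <- mass_calibration(alpha = cfg$calibration$alpha_m3_per_kg,
                          wavelength = cfg$acquisition$wavelength_m)
  empty_ids <- cfg$stats$empty_ids
  phases <- lapply(phases, background_correct, background_region = background)
  table <- measure_stack(phases, mask, empty_ids = unlist(empty_ids), cal = cal)
  write_measurements_csv(table, file.path(cfg$paths$output_dir,
                                          "measurements.csv"))
  write_mask_tiff(mask, file.path(cfg$paths$output_dir, "mask.tif"))

  frames <- sort(unique(table$frame))
  scv <- vapply(frames, function(f) spatial_cv(table, f), numeric(1))
  summary <- data.frame(
    statistic = c("median_trap_optical_volume", "median_spatial_cv",
                  if (length(frames) > 1) "temporal_cv"),
    value = c(stats::median(table$optical_volume_um3[!table$occupied]),
              stats::median(scv),
              if (length(frames) > 1) temporal_cv(table)),
    units = c("um3", "percent", if (length(frames) > 1) "percent"),
    n = c(sum(!table$occupied), length(scv),
          if (length(frames) > 1) length(frames)))
  utils::write.csv(summary, file.path(cfg$paths$output_dir, "summary.csv"),
                   row.names = FALSE)
  write_provenance(cfg$paths$output_dir, "measure", cfg)
  invisible(table)
}

#' Fit cell growth from a measurement table
#'
#' Builds per-cell mass tracks (traps occupied in every frame), normalizes
#' each by its initial mass, averages across cells, and fits the
#' exponential growth rate by log-linear least squares. Writes
#' `growth_report.csv` (rate, doubling time, per-cell mass CV) and
#' `normalized_mass.csv`.
#'
#' @param measurements Path to a measurements CSV, or the table itself.
#' @param out_dir Output directory.
#' @param dt_min Frame interval in minutes (default 5).
#' @return Invisibly, a list with `rate`, `doubling_time`, `per_cell_cv`
#'   (median per-cell mass CV, percent) and the averaged track.
#' @export
run_growth <- function(measurements, out_dir, dt_min = 5) {
  table <- if (is.character(measurements)) read_measurements_csv(measurements)
           else measurements
  if (length(unique(table$frame)) < 2L)
    stop("growth fitting needs at least 2 frames")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tracks <- extract_mass_tracks(table, dt_min = dt_min)
  avg <- normalize_and_average(tracks)
  fit <- fit_growth_rate(avg$time_h, avg$mean_normalized_mass)
  cv <- vapply(split(tracks$mass_pg, tracks$trap_id),
               coefficient_of_variation, numeric(1))
  report <- data.frame(
    statistic = c("growth_rate", "doubling_time", "median_per_cell_mass_cv",
                  "n_cells"),
    value = c(fit$rate, fit$doubling_time, stats::median(cv),
              avg$n_cells[1]),
    units = c("1/h", "h", "percent", "cells"),
    n = c(nrow(avg), nrow(avg), length(cv), avg$n_cells[1]))
  utils::write.csv(report, file.path(out_dir, "growth_report.csv"),
                   row.names = FALSE)
  utils::write.csv(avg, file.path(out_dir, "normalized_mass.csv"),
                   row.names = FALSE)
  invisible(list(rate = fit$rate, doubling_time = fit$doubling_time,
                 per_cell_cv = stats::median(cv), average = avg))
}
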