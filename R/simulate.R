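# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# --- exact disc/pixel coverage -------------------------------------------

# Antiderivative of sqrt(r^2 - x^2), valid for 0 <= x <= r.
.chord_int <- function(x, r) {
  x <- pmin(x, r)
  0.5 * (x * sqrt(pmax(r * r - x * x, 0)) + r * r * asin(pmin(x / r, 1)))
}

# Area of disk (radius r, centered at origin) intersected with the
# first-quadrant rectangle [x0,x1] x [y0,y1], 0 <= x0 <= x1, 0 <= y0 <= y1.
# Vectorized over rectangles.
.quad_area <- function(x0, x1, y0, y1, r) {
  xmax <- sqrt(pmax(r * r - y0 * y0, 0))   # beyond: circle below y0
  xb <- pmin(x1, xmax)
  xc <- sqrt(pmax(r * r - y1 * y1, 0))     # before: circle above y1
  part1 <- y1 * pmax(pmin(xb, xc) - x0, 0)
  lo <- pmax(x0, pmin(xc, xb))
  hi <- pmax(xb, lo)
  part2 <- .chord_int(hi, r) - .chord_int(lo, r)
  base <- y0 * pmax(xb - x0, 0)
  pmax(part1 + part2 - base, 0)
}

# Area of disk (radius r at origin) intersected with rectangles
# [x0,x1] x [y0,y1] of any sign; split at the axes and fold into the first
# quadrant. Vectorized.
disc_rect_area <- function(x0, x1, y0, y1, r) {
  xs <- list(c1 = cbind(pmax(x0, 0), pmax(x1, 0)),
             c2 = cbind(pmax(-x1, 0), pmax(-x0, 0)))
  ys <- list(c1 = cbind(pmax(y0, 0), pmax(y1, 0)),
             c2 = cbind(pmax(-y1, 0), pmax(-y0, 0)))
  a <- 0
  for (X in xs) for (Y in ys)
    a <- a + .quad_area(X[, 1], X[, 2], Y[, 1], Y[, 2], r)
  a
}

# Add a disc of uniform "amplitude" (optical thickness) to a thickness
# matrix using exact pixel-area weighting. Pixel centers sit at 0-based
# integer coordinates times pixel_size (um); each pixel spans +/- px/2.
# Returns the updated matrix; the added discrete integral equals
# amplitude * pi * r^2 exactly (up to floating point).
add_disc <- function(thickness, pixel_size, center_row_um, center_col_um,
                     radius_um, amplitude) {
  nr <- nrow(thickness); nc <- ncol(thickness)
  px <- pixel_size
  r0 <- max(0L, floor((center_row_um - radius_um) / px - 0.5))
  r1 <- min(nr - 1L, ceiling((center_row_um + radius_um) / px + 0.5))
  c0 <- max(0L, floor((center_col_um - radius_um) / px - 0.5))
  c1 <- min(nc - 1L, ceiling((center_col_um + radius_um) / px + 0.5))
  if (r1 < r0 || c1 < c0) return(thickness)
  rows <- r0:r1; cols <- c0:c1
  ylo <- rows * px - px / 2 - center_row_um
  xlo <- cols * px - px / 2 - center_col_um
  Y0 <- matrix(ylo, length(rows), length(cols))
  X0 <- matrix(xlo, length(rows), length(cols), byrow = TRUE)
  area <- disc_rect_area(as.vector(X0), as.vector(X0) + px,
                         as.vector(Y0), as.vector(Y0) + px, radius_um)
  thickness[rows + 1L, cols + 1L] <- thickness[rows + 1L, cols + 1L] +
    amplitude * matrix(area, length(rows), length(cols)) / px^2
  thickness
}

# Spherical-cap optical-thickness profile over the pixel grid: peak
# amplitude times sqrt(1 - (rho/R)^2). Returned as a full-size matrix (only
# the bounding box is touched). The discrete integral is normalized to the
# analytic (2/3) pi R^2 * amplitude so ground truth and rendering agree
# exactly.
add_cap <- function(thickness, pixel_size, center_row_um, center_col_um,
                    radius_um, amplitude) {
  nr <- nrow(thickness); nc <- ncol(thickness)
  px <- pixel_size
  r0 <- max(0L, floor((center_row_um - radius_um) / px))
  r1 <- min(nr - 1L, ceiling((center_row_um + radius_um) / px))
  c0 <- max(0L, floor((center_col_um - radius_um) / px))
  c1 <- min(nc - 1L, ceiling((center_col_um + radius_um) / px))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows * px - center_row_um
  dx <- cols * px - center_col_um
  rho2 <- outer(dy^2, dx^2, "+")
  p <- sqrt(pmax(1 - rho2 / radius_um^2, 0))
  target <- (2 / 3) * pi * radius_um^2 * amplitude
  s <- sum(p) * px^2
  if (s <= 0) stop("cell cap does not cover any pixel; decrease pixel size")
  thickness[rows + 1L, cols + 1L] <- thickness[rows + 1L, cols + 1L] +
    p * (target / s)
  thickness
}

#' Simulation configuration
#'
#' Describes the synthetic device and acquisition: a rhombic array of
#' hydrodynamic traps (each trap two identical vertical cylinders with a
#' small gap), optical properties of polymer and medium, an optional
#' trapped-cell model (spherical-cap optical-thickness bump), noise terms,
#' and the time-lapse schedule. Defaults describe the reference device: 150
#' traps (15 x 10), 7.5 um cylinder radius, 9.8 um channel height, index
#' difference 0.0241 to water, imaged every 5 min for 18 h with cells
#' growing exponentially at 0.021 1/h.
#'
#' @param pixel_size um per pixel.
#' @param margin Margin around the trap array, um.
#' @param pitch_u,pitch_v Lattice pitch along columns / rows, um.
#' @param counts_u,counts_v Number of traps per lattice direction.
#' @param radius,gap,height Cylinder radius, inter-cylinder gap, and channel
#'   height, um.
#' @param cylinders_per_trap Cylinders per trap (2: a pair with a gap).
#' @param n_material,n_medium Refractive indices of polymer and medium.
#' @param cell_radius Trapped-cell footprint radius, um.
#' @param cell_peak_thickness Peak optical thickness of the cell bump, um;
#'   the cell optical volume is `(2/3) pi cell_radius^2` times this.
#' @param occupancy_prob Probability a trap holds a cell.
#' @param trap_cv Trap-to-trap fractional volume variability (fabrication
#'   spread; sets the spatial CV).
#' @param frame_jitter_cv Per-frame multiplicative jitter on the whole
#'   field (focus/illumination drift; sets the temporal CV).
#' @param mult_sigma,add_sigma Per-pixel multiplicative / additive noise on
#'   synthesized DPC intensity images.
#' @param frames,dt_min Number of frames and frame interval (minutes).
#' @param growth_rate Exponential cell growth rate, 1/h.
#' @param gradient_gain,i0 DPC forward-model gain and mean intensity.
#' @param wavelength Illumination wavelength, m.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(pixel_size = 0.5, margin = 30,
                       pitch_u = 50, pitch_v = 40,
                       counts_u = 15, counts_v = 10,
                       radius = 7.5, gap = 4, height = 9.8,
                       cylinders_per_trap = 2L,
                       n_material = 1.3541, n_medium = 1.330,
                       cell_radius = 8, cell_peak_thickness = 0.403,
                       occupancy_prob = 0.3,
                       trap_cv = 0.042, frame_jitter_cv = 0.018,
                       mult_sigma = 0, add_sigma = 0,
                       frames = 217, dt_min = 5, growth_rate = 0.021,
                       gradient_gain = 1.0, i0 = 0.5,
                       wavelength = 624e-9, seed = 1L) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("trap_cv", "frame_jitter_cv", "mult_sigma",
                       "add_sigma")]) < 0))
    stop("noise sigmas must be >= 0")
  if (pixel_size <= 0 || radius <= 0 || height <= 0)
    stop("pixel_size, radius and height must be positive")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Lattice of the simulated device in pixel coordinates.
sim_lattice <- function(config) {
  px <- config$pixel_size
  origin <- c(config$margin, config$margin) / px
  fit_lattice(origin,
              origin + c(0, config$pitch_u / px),
              origin + c(config$pitch_v / px, 0),
              config$counts_u, config$counts_v)
}

# Image shape implied by the config.
sim_shape <- function(config) {
  px <- config$pixel_size
  nr <- round((2 * config$margin + (config$counts_v - 1) * config$pitch_v) / px) + 1
  nc <- round((2 * config$margin + (config$counts_u - 1) * config$pitch_u) / px) + 1
  c(nr, nc)
}

#' Render the synthetic trap-array optical-thickness field
#'
#' Every trap is `cylinders_per_trap` cylinders of radius `radius`
#' (centered on the trap center, offset `+/- (gap/2 + radius)` along the
#' first lattice direction for a pair) with uniform optical thickness
#' `height * delta_n` (polymer pillars positive against water). Cylinder
#' footprints use exact pixel-area weighting, so the discrete integral of
#' each trap equals its analytic optical volume
#' `cylinders * pi r^2 h delta_n` (times the per-trap fabrication factor)
#' to floating-point accuracy. Per-trap factors `1 + N(0, trap_cv)` model
#' fabrication spread and are drawn under `config$seed`.
#'
#' @param config A [sim_config].
#' @return List with `phase` (a [phase_image]), `truth` (data frame:
#'   `trap_id`, `row`, `col` in 0-based px, `factor`, `trap_volume_um3`,
#'   `occupied`, `cell_volume_um3`, `cell_mass_pg`), and `lattice`.
#' @export
render_trap_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  px <- config$pixel_size
  shape <- sim_shape(config)
  lat <- sim_lattice(config)
  centers <- lattice_centers(lat)
  n <- nrow(centers)
  dn <- config$n_material - config$n_medium
  amp <- config$height * dn
  factor <- with_seed(config$seed, pmax(1 + stats::rnorm(n, 0, config$trap_cv), 0.1))

  th <- matrix(0, shape[1], shape[2])
  k <- config$cylinders_per_trap
  offsets <- if (k == 1L) 0 else
    (seq_len(k) - (k + 1) / 2) * (2 * config$radius + config$gap)
  for (t in seq_len(n)) {
    for (off in offsets) {
      th <- add_disc(th, px,
                     centers$row[t] * px,
                     centers$col[t] * px + off,
                     config$radius, amp * factor[t])
    }
  }
  vol <- k * pi * config$radius^2 * config$height * dn * factor
  truth <- data.frame(trap_id = centers$trap_id,
                      row = centers$row, col = centers$col,
                      factor = factor, trap_volume_um3 = vol,
                      occupied = FALSE,
                      cell_volume_um3 = NA_real_, cell_mass_pg = NA_real_)
  list(phase = phase_image(th, px, config$wavelength),
       truth = truth, lattice = lat)
}

#' Add trapped cells to a rendered field
#'
#' Occupied traps receive a spherical-cap optical-thickness bump centered
#' on the trap (footprint radius `cell_radius`, peak `cell_peak_thickness`,
#' optical volume `(2/3) pi R^2 * peak`). The rendered discrete integral is
#' normalized to the analytic volume, so ground-truth masses (volume / 0.18
#' um^3/pg) are exact by construction.
#'
#' @param field Output of [render_trap_field()].
#' @param config A [sim_config].
#' @param occupied_ids Optional trap ids to occupy; default: Bernoulli
#'   draws with `occupancy_prob` under `config$seed + 1`.
#' @param cell_volumes Optional per-cell optical volumes (um^3), recycled
#'   over occupied traps; default from the cap geometry.
#' @return Updated `field` list (phase, truth, lattice).
#' @export
add_cells <- function(field, config, occupied_ids = NULL, cell_volumes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- field$truth
  if (is.null(occupied_ids)) {
    occ <- with_seed(config$seed + 1L,
                     stats::runif(nrow(truth)) < config$occupancy_prob)
    occupied_ids <- truth$trap_id[occ]
  }
  if (length(occupied_ids) == 0L) return(field)
  vol0 <- (2 / 3) * pi * config$cell_radius^2 * config$cell_peak_thickness
  if (is.null(cell_volumes)) cell_volumes <- vol0
  cell_volumes <- rep_len(cell_volumes, length(occupied_ids))
  th <- field$phase$optical_thickness
  px <- field$phase$pixel_size
  for (i in seq_along(occupied_ids)) {
    t <- match(occupied_ids[i], truth$trap_id)
    peak <- config$cell_peak_thickness * cell_volumes[i] / vol0
    th <- add_cap(th, px, truth$row[t] * px, truth$col[t] * px,
                  config$cell_radius, peak)
    truth$occupied[t] <- TRUE
    truth$cell_volume_um3[t] <- cell_volumes[i]
    truth$cell_mass_pg[t] <- cell_volumes[i] / 0.18
  }
  field$phase$optical_thickness <- th
  field$truth <- truth
  field
}

#' Forward DPC model: phase gradients to DPC signals
#'
#' Applies the same linear gradient model the reconstructor inverts:
#' `signal_axis = gain * d(thickness)/d(axis)` with circular central
#' differences (per-pixel spacing). Exact adjoint of
#' [reconstruct_phase()]'s operator, so noise-free round trips are limited
#' only by the regularization.
#'
#' @param field A [phase_image].
#' @param params A [recon_params] (only `gradient_gain` is used).
#' @return List `sig_x`, `sig_y` of [dpc_signal]s.
#' @export
forward_dpc <- function(field, params = recon_params()) {
  stopifnot(inherits(field, "phase_image"), inherits(params, "recon_params"))
  g <- params$gradient_gain
  list(sig_x = dpc_signal(g * central_diff(field$optical_thickness, "horizontal"),
                          "horizontal"),
       sig_y = dpc_signal(g * central_diff(field$optical_thickness, "vertical"),
                          "vertical"))
}

#' Synthesize half-illumination intensity image pairs
#'
#' Intensities are `i0 * (1 +/- gain * gradient)`, clipped at 0, with
#' optional per-pixel multiplicative and additive Gaussian noise
#' (`mult_sigma`, `add_sigma * i0`) applied independently to each image.
#'
#' @param field A [phase_image].
#' @param config A [sim_config] (uses `gradient_gain`, `i0`, `mult_sigma`,
#'   `add_sigma`, `seed`).
#' @param seed Seed for the noise draws (default `config$seed + 2`).
#' @return List `horizontal`, `vertical` of [dpc_image_pair]s.
#' @export
forward_dpc_pairs <- function(field, config, seed = config$seed + 2L) {
  stopifnot(inherits(field, "phase_image"), inherits(config, "sim_config"))
  sig <- forward_dpc(field, recon_params(gradient_gain = config$gradient_gain))
  mk <- function(values, axis) {
    ia <- config$i0 * (1 + values)
    ib <- config$i0 * (1 - values)
    if (config$mult_sigma > 0 || config$add_sigma > 0) {
      noise <- function(m)
        pmax(m * (1 + stats::rnorm(length(m), 0, config$mult_sigma)) +
               stats::rnorm(length(m), 0, config$add_sigma * config$i0), 0)
      ia[] <- noise(ia); ib[] <- noise(ib)
    }
    dpc_image_pair(pmax(ia, 0), pmax(ib, 0), axis)
  }
  with_seed(seed, list(horizontal = mk(sig$sig_x$values, "horizontal"),
                       vertical = mk(sig$sig_y$values, "vertical")))
}

#' Simulate a time-lapse of the trapped-cell field
#'
#' The trap field is static; trapped-cell masses grow exponentially,
#' `m(t) = m0 * exp(rate * t)` (the cell bump amplitude is scaled
#' accordingly), and each frame is multiplied by a per-frame jitter factor
#' `1 + N(0, frame_jitter_cv)` modeling focus/illumination drift. Fully
#' deterministic under `config$seed`.
#'
#' @param config A [sim_config].
#' @param occupied_ids,cell_volumes Passed to [add_cells()].
#' @param frame_callback Optional `function(frame_index, phase)`; when
#'   given, frames are streamed to it and not retained (for writing long
#'   stacks without holding them in memory).
#' @return List with `phases` (list of [phase_image]s, or `NULL` when
#'   streaming), `truth` (per-frame data frame with `frame`, `time_h`,
#'   `jitter` columns added), `lattice`, `config`.
#' @export
simulate_timelapse <- function(config, occupied_ids = NULL,
                               cell_volumes = NULL, frame_callback = NULL) {
  stopifnot(inherits(config, "sim_config"))
  base <- render_trap_field(config)
  zero <- matrix(0, nrow(base$phase$optical_thickness),
                 ncol(base$phase$optical_thickness))
  cellf <- base
  cellf$phase$optical_thickness <- zero
  cellf <- add_cells(cellf, config, occupied_ids = occupied_ids,
                     cell_volumes = cell_volumes)
  cell_th <- cellf$phase$optical_thickness
  truth0 <- cellf$truth
  truth0$trap_volume_um3 <- base$truth$trap_volume_um3

  jit <- with_seed(config$seed + 3L,
                   1 + stats::rnorm(config$frames, 0, config$frame_jitter_cv))
  keep <- is.null(frame_callback)
  phases <- if (keep) vector("list", config$frames) else NULL
  truth <- vector("list", config$frames)
  for (f in seq_len(config$frames)) {
    t_h <- (f - 1) * config$dt_min / 60
    scale <- exp(config$growth_rate * t_h)
    th <- (base$phase$optical_thickness + cell_th * scale) * jit[f]
    ph <- phase_image(th, config$pixel_size, config$wavelength)
    if (keep) phases[[f]] <- ph else frame_callback(f, ph)
    tf <- truth0
    tf$cell_volume_um3 <- tf$cell_volume_um3 * scale
    tf$cell_mass_pg <- tf$cell_mass_pg * scale
    tf <- cbind(frame = f, time_h = t_h, jitter = jit[f], tf)
    truth[[f]] <- tf
  }
  list(phases = phases, truth = do.call(rbind, truth),
       lattice = base$lattice, config = config)
}
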