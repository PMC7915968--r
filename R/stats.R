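#' Coefficient of variation (percent)
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, times
#' 100. Scale-invariant for positive scalings; the repeatability metric
#' used throughout.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values for a CV")
  mu <- mean(values)
  if (mu == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / mu
}

#' Spatial repeatability: CV across empty traps within one frame
#'
#' @param table Measurement table from [measure_traps()] /
#'   [measure_stack()].
#' @param frame Frame index to evaluate (default: first frame present).
#' @return CV in percent across the empty-trap optical volumes of that
#'   frame.
#' @export
spatial_cv <- function(table, frame = NULL) {
  if (is.null(frame)) frame <- min(table$frame)
  v <- table$optical_volume_um3[table$frame == frame & !table$occupied]
  if (length(v) < 2L) stop("need at least 2 empty traps in the frame")
  coefficient_of_variation(v)
}

#' Temporal repeatability: CV across frames of the mean empty-trap volume
#'
#' The per-frame mean optical volume of empty traps is computed first; the
#' CV is taken across frames. Per-trap temporal CVs are available from
#' [temporal_cv_per_trap()].
#'
#' @param table Measurement table spanning >= 2 frames.
#' @return CV in percent.
#' @export
temporal_cv <- function(table) {
  empty <- table[!table$occupied, ]
  means <- tapply(empty$optical_volume_um3, empty$frame, mean)
  if (length(means) < 2L) stop("need at least 2 frames")
  coefficient_of_variation(as.numeric(means))
}

#' Per-trap temporal CV
#'
#' @param table Measurement table spanning >= 2 frames.
#' @return Data frame (`trap_id`, `cv_pct`) over traps present in >= 2
#'   frames, using total trap optical volume.
#' @export
temporal_cv_per_trap <- function(table) {
  sp <- split(table$optical_volume_um3, table$trap_id)
  sp <- sp[vapply(sp, length, 1L) >= 2L]
  data.frame(trap_id = as.integer(names(sp)),
             cv_pct = vapply(sp, coefficient_of_variation, numeric(1)),
             row.names = NULL)
}

#' Five-number boxplot summary with 1.5 x IQR outlier rule
#'
#' Quartiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7). Outliers are points more than 1.5 x IQR
#' above the third or below the first quartile; whiskers are the extreme
#' data points that are not outliers.
#'
#' @param values Numeric vector, length >= 5.
#' @return Object of class `boxplot_summary`: `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 5L) stop("need at least 5 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values < lo | values > hi
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(values[!out]),
                 whisker_high = max(values[!out]),
                 outliers = values[out]),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf("median %.4g [q1 %.4g, q3 %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

#' Extract per-cell mass tracks from a measurement table
#'
#' Keeps traps that are occupied in every frame (cells pinned by the traps
#' do not move, so trap id identifies the cell throughout).
#'
#' Tracks whose mass is not strictly above `min_mass_pg` in every frame are
#' dropped: auto-classified occupancy can flag an outlying *empty* trap as
#' occupied, and such traps carry near-zero (possibly negative) apparent
#' cell mass that cannot be normalized.
#'
#' @param table Measurement table from [measure_stack()].
#' @param dt_min Frame interval in minutes (default 5).
#' @param min_mass_pg Exclusive lower bound on every mass in a retained
#'   track (default 0).
#' @return Long data frame (`trap_id`, `time_h`, `mass_pg`).
#' @export
extract_mass_tracks <- function(table, dt_min = 5, min_mass_pg = 0) {
  frames <- sort(unique(table$frame))
  occ <- table[table$occupied, ]
  keep <- names(which(tapply(occ$frame, occ$trap_id,
                             function(f) length(unique(f))) == length(frames)))
  occ <- occ[occ$trap_id %in% as.integer(keep), ]
  pos <- names(which(tapply(occ$cell_mass_pg, occ$trap_id,
                            function(m) all(m > min_mass_pg))))
  occ <- occ[occ$trap_id %in% as.integer(pos), ]
  if (nrow(occ) == 0L) stop("no trap is occupied in every frame")
  occ <- occ[order(occ$trap_id, occ$frame), ]
  data.frame(trap_id = occ$trap_id,
             time_h = (match(occ$frame, frames) - 1L) * dt_min / 60,
             mass_pg = occ$cell_mass_pg)
}

#' Normalize mass tracks by initial mass and average across cells
#'
#' Each cell's mass series is divided by its mass at the first time point,
#' then the normalized series are averaged pointwise across cells. The
#' averaged series is exactly 1 at the first time point.
#'
#' @param tracks Long data frame (`trap_id`, `time_h`, `mass_pg`) on a
#'   common time grid; initial mass of every track must be > 0.
#' @return Data frame (`time_h`, `mean_normalized_mass`, `n_cells`).
#' @export
normalize_and_average <- function(tracks) {
  sp <- split(tracks, tracks$trap_id)
  times <- sort(unique(tracks$time_h))
  norm <- lapply(sp, function(d) {
    d <- d[order(d$time_h), ]
    if (!isTRUE(all.equal(d$time_h, times)))
      stop("tracks must share a common time grid")
    if (d$mass_pg[1] <= 0) stop("initial mass must be positive")
    d$mass_pg / d$mass_pg[1]
  })
  m <- do.call(cbind, norm)
  data.frame(time_h = times,
             mean_normalized_mass = rowMeans(m),
             n_cells = ncol(m))
}

#' Fit an exponential growth rate by log-linear least squares
#'
#' Fits `ln(mass) ~ time` by ordinary least squares; the slope is the
#' exponential growth rate (1/h) and the doubling time is `ln(2) / rate`
#' (reported only for positive rates).
#'
#' @param time_h Time points in hours (>= 10 points).
#' @param mass Masses (or normalized masses), all > 0.
#' @return List with `rate` (1/h) and `doubling_time` (h, `NA` if rate
#'   <= 0).
#' @export
fit_growth_rate <- function(time_h, mass) {
  if (length(time_h) != length(mass)) stop("time and mass lengths differ")
  if (length(time_h) < 10L) stop("need at least 10 time points")
  if (any(mass <= 0)) stop("masses must be positive for a log fit")
  fit <- stats::lm.fit(cbind(1, time_h), log(mass))
  rate <- unname(fit$coefficients[2])
  if (abs(rate) < 1e-12) rate <- 0  # constant-mass tie-break
  list(rate = rate,
       doubling_time = if (rate > 0) log(2) / rate else NA_real_)
}
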