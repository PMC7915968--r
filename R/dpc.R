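#' Differential phase contrast (DPC) image pair
#'
#' A pair of intensity images taken under complementary half-circle
#' illumination along one axis. The normalized difference of the two images
#' encodes the phase gradient along that axis.
#'
#' @param intensity_a Numeric matrix of non-negative intensities (arbitrary
#'   counts): the "right"/top-half illumination image.
#' @param intensity_b Matrix of the same shape: the complementary
#'   "left"/bottom-half illumination image.
#' @param axis `"horizontal"` (gradient along columns) or `"vertical"`
#'   (gradient along rows).
#' @return An object of class `dpc_image_pair`.
#' @export
dpc_image_pair <- function(intensity_a, intensity_b, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (!is.matrix(intensity_a) || !is.matrix(intensity_b))
    stop("intensities must be matrices")
  if (!identical(dim(intensity_a), dim(intensity_b)))
    stop("intensity images must have the same shape")
  if (!all(is.finite(intensity_a)) || !all(is.finite(intensity_b)))
    stop("intensities must be finite")
  if (any(intensity_a < 0) || any(intensity_b < 0))
    stop("intensities must be non-negative")
  if (!any(intensity_a + intensity_b > 0))
    stop("at least one pixel must have non-zero total intensity")
  structure(list(intensity_a = intensity_a, intensity_b = intensity_b,
                 axis = axis),
            class = "dpc_image_pair")
}

#' DPC signal for one illumination axis
#'
#' @param values Numeric matrix in [-1, 1]; `NA` marks pixels where the
#'   signal is undefined (zero total intensity).
#' @param axis `"horizontal"` or `"vertical"`.
#' @return An object of class `dpc_signal`.
#' @export
dpc_signal <- function(values, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (!is.matrix(values)) stop("values must be a matrix")
  if (any(abs(values) > 1, na.rm = TRUE))
    stop("DPC signal values must lie in [-1, 1]")
  structure(list(values = values, axis = axis), class = "dpc_signal")
}

#' Compute the normalized DPC signal from an image pair
#'
#' Pixelwise `(I_a - I_b) / (I_a + I_b)`. The result is bounded in
#' \[-1, 1\] wherever the total intensity is positive; pixels with zero
#' total intensity are flagged undefined (`NA`), never silently set to 0.
#'
#' @param pair A [dpc_image_pair].
#' @return A [dpc_signal] with the same axis label.
#' @export
compute_dpc_signal <- function(pair) {
  stopifnot(inherits(pair, "dpc_image_pair"))
  tot <- pair$intensity_a + pair$intensity_b
  v <- (pair$intensity_a - pair$intensity_b) / tot
  v[tot == 0] <- NA_real_
  dpc_signal(v, pair$axis)
}

#' Reconstruction parameters for DPC phase integration
#'
#' @param gradient_gain Linear DPC sensitivity `g` relating the signal to
#'   the optical-thickness gradient per pixel (dimensionless, non-zero).
#' @param regularization Tikhonov weight on the Fourier least-squares
#'   integration, dimensionless and >= 0. Damps poorly conditioned
#'   low-frequency modes when signals are noisy; use 0 for noise-free data.
#' @param background_anchor Region specification used to pin the additive
#'   phase constant (the mean over this region is set to 0), or `NULL` to
#'   anchor on the whole-image mean.
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(gradient_gain = 1.0, regularization = 1e-4,
                         background_anchor = NULL) {
  if (!is.numeric(gradient_gain) || length(gradient_gain) != 1L ||
      gradient_gain == 0)
    stop("gradient_gain must be a single non-zero number")
  if (!is.numeric(regularization) || length(regularization) != 1L ||
      regularization < 0)
    stop("regularization must be a single number >= 0")
  structure(list(gradient_gain = gradient_gain,
                 regularization = regularization,
                 background_anchor = background_anchor),
            class = "recon_params")
}

# Circular central difference along columns (x) or rows (y); the gradient
# convention shared bit-for-bit by the simulator's forward model and the
# Fourier integrator (whose symbol is i*sin(2*pi*k/N)).
central_diff <- function(m, axis) {
  if (axis == "horizontal") {
    nc <- ncol(m)
    (m[, c(2:nc, 1), drop = FALSE] - m[, c(nc, 1:(nc - 1)), drop = FALSE]) / 2
  } else {
    nr <- nrow(m)
    (m[c(2:nr, 1), , drop = FALSE] - m[c(nr, 1:(nr - 1)), , drop = FALSE]) / 2
  }
}

# Replace isolated undefined pixels by the mean of their defined 4-neighbors.
# Errors if undefined pixels exceed max_frac of the image.
inpaint_undefined <- function(m, max_frac = 0.05) {
  bad <- is.na(m)
  if (!any(bad)) return(m)
  if (mean(bad) > max_frac)
    stop(sprintf("undefined pixels exceed %.0f%% of the image", 100 * max_frac))
  nr <- nrow(m); nc <- ncol(m)
  # a few sweeps handle small clusters; isolated pixels resolve in one
  for (sweep in 1:8) {
    bad <- which(is.na(m), arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    fill <- numeric(nrow(bad))
    ok <- logical(nrow(bad))
    for (i in seq_len(nrow(bad))) {
      r <- bad[i, 1]; c <- bad[i, 2]
      nb <- c(if (r > 1) m[r - 1, c], if (r < nr) m[r + 1, c],
              if (c > 1) m[r, c - 1], if (c < nc) m[r, c + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb) > 0) { fill[i] <- mean(nb); ok[i] <- TRUE }
    }
    m[bad[ok, , drop = FALSE]] <- fill[ok]
    if (all(ok)) break
  }
  if (anyNA(m)) stop("could not inpaint undefined pixels (cluster too large)")
  m
}

#' Reconstruct the optical-thickness map from two orthogonal DPC signals
#'
#' Inverts the linear gradient model `signal_axis = g * d(thickness)/d(axis)`
#' (circular central differences, matching [forward_dpc()]) by least-squares
#' integration in the Fourier domain with Tikhonov regularization:
#' each Fourier mode of the thickness is
#' `(conj(Dx) Sx + conj(Dy) Sy) / (|Dx|^2 + |Dy|^2 + reg)`, where
#' `D` is the central-difference symbol `i*sin(2*pi*k/N)` and `S` the
#' transform of the gain-normalized signal. The additive constant, which the
#' gradient data cannot determine, is fixed by forcing the mean over
#' `params$background_anchor` to 0. Because signals are divided by the gain
#' before integration, the gain cancels exactly in a simulate-reconstruct
#' round trip.
#'
#' Isolated undefined pixels in either signal are inpainted by their
#' 4-neighbor mean; more than 5% undefined pixels is an error.
#'
#' @param sig_x,sig_y [dpc_signal]s with distinct axes (one horizontal, one
#'   vertical) and identical shape.
#' @param params A [recon_params].
#' @param pixel_size Pixel size in um.
#' @param wavelength Wavelength in metres (metadata).
#' @return A [phase_image] with optical thickness in um.
#' @export
reconstruct_phase <- function(sig_x, sig_y, params = recon_params(),
                              pixel_size, wavelength = 624e-9) {
  stopifnot(inherits(sig_x, "dpc_signal"), inherits(sig_y, "dpc_signal"),
            inherits(params, "recon_params"))
  if (sig_x$axis == sig_y$axis)
    stop("the two signals must have distinct axes")
  if (sig_x$axis == "vertical") { tmp <- sig_x; sig_x <- sig_y; sig_y <- tmp }
  if (!identical(dim(sig_x$values), dim(sig_y$values)))
    stop("signals must have the same shape")

  g <- params$gradient_gain
  dx <- inpaint_undefined(sig_x$values) / g
  dy <- inpaint_undefined(sig_y$values) / g

  nr <- nrow(dx); nc <- ncol(dx)
  # central-difference symbols: columns index x-frequency, rows y-frequency
  ex <- 1i * sin(2 * pi * (0:(nc - 1)) / nc)
  ey <- 1i * sin(2 * pi * (0:(nr - 1)) / nr)
  DX <- matrix(ex, nr, nc, byrow = TRUE)
  DY <- matrix(ey, nr, nc)

  num <- Conj(DX) * stats::fft(dx) + Conj(DY) * stats::fft(dy)
  den <- Re(DX * Conj(DX) + DY * Conj(DY)) + params$regularization
  frac <- num
  nz <- den > 0
  frac[nz] <- num[nz] / den[nz]
  frac[!nz] <- 0  # modes the gradient operator cannot see (DC, shared Nyquist)
  t <- Re(stats::fft(frac, inverse = TRUE)) / (nr * nc)

  anchor <- params$background_anchor
  reg <- if (is.null(anchor)) matrix(TRUE, nr, nc) else resolve_region(anchor, c(nr, nc))
  if (!any(reg)) stop("background_anchor region is empty")
  t <- t - mean(t[reg])
  phase_image(t, pixel_size = pixel_size, wavelength = wavelength)
}
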