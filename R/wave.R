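# Independent wave-optics oracle: scalar angular-spectrum propagation of the
# masked, object-modulated wavefield, followed by source blur and pixel
# binning. The propagation is 1-D in x per detector row, exploiting the
# mask's one-dimensional modulation; diffraction along y is negligible for
# the slowly varying phantoms this oracle is meant for (feature scales much
# larger than sqrt(lambda z), a few microns here).

new_complex_field <- function(values, dx) {
  stopifnot(is.matrix(values), is.complex(values), is.numeric(dx), dx > 0)
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("complex field must be finite")
  }
  structure(list(values = values, dx = dx), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d samples, dx = %.3g m, total power %.6g\n",
              nrow(x$values), ncol(x$values), x$dx,
              sum(Mod(x$values)^2) * x$dx))
  invisible(x)
}

#' Wavefield just downstream of object and mask
#'
#' The mask is treated as a pure absorber and the object as a thin phase
#' screen: `U = sqrt(T M(x)) exp(i phi)`, so that `|U|^2 = T M` exactly.
#' Binary masks are evaluated with their exact square-wave profile.
#'
#' @param obj A `projected_object`.
#' @param spec A `mask_spec`.
#' @param x Optional fine-grid x coordinates (defaults to the object's own
#'   grid starting at x = 0).
#' @return A `complex_field` (rows = y, columns = x).
#' @export
object_exit_field <- function(obj, spec, x = NULL) {
  stopifnot(inherits(obj, "projected_object"), inherits(spec, "mask_spec"))
  if (is.null(x)) x <- (seq_len(ncol(obj$T)) - 0.5) * obj$dx
  M <- mask_transmission(spec, x, exact = TRUE)
  I0 <- sweep(obj$T, 2, M, `*`)
  if (any(I0 < 0)) stop("negative transmitted intensity T * M")
  U <- sqrt(I0) * exp(1i * obj$phi)
  new_complex_field(U, obj$dx)
}

#' Angular-spectrum free-space propagation (1-D in x, per row)
#'
#' Applies the exact scalar transfer function
#' `H(f) = exp(i k z (sqrt(1 - (lambda f)^2) - 1))` in the spatial-frequency
#' domain along x, independently for each row. Evanescent components
#' (`|lambda f| > 1`) are zeroed. Boundary conditions are periodic (FFT);
#' callers must provide guard bands if the field is not periodic. A warning
#' is issued when `z` exceeds the standard aliasing bound `N dx^2 / lambda`
#' (conservative for smooth, band-limited fields).
#'
#' @param field A `complex_field`.
#' @param wavelength Wavelength (m).
#' @param z Propagation distance (m); 0 is the identity.
#' @return A propagated `complex_field`.
#' @export
angular_spectrum <- function(field, wavelength, z) {
  stopifnot(inherits(field, "complex_field"), wavelength > 0)
  if (z == 0) return(field)
  v <- field$values
  n <- ncol(v)
  dx <- field$dx
  if (abs(z) > n * dx^2 / wavelength) {
    warning(sprintf("propagation distance %.3g m exceeds the angular-spectrum aliasing guard %.3g m for this grid",
                    z, n * dx^2 / wavelength))
  }
  f <- (((seq_len(n) - 1) + floor(n / 2)) %% n - floor(n / 2)) / (n * dx)
  arg <- 1 - (wavelength * f)^2
  k <- 2 * pi / wavelength
  H <- ifelse(arg >= 0, exp(1i * k * z * (sqrt(pmax(arg, 0)) - 1)), 0 + 0i)
  spec <- t(stats::mvfft(t(v)))
  out <- t(stats::mvfft(t(sweep(spec, 2, H, `*`)), inverse = TRUE)) / n
  new_complex_field(out, dx)
}

# cosine taper from 1 (inner edge of guard) to 0 (outer edge)
guard_taper <- function(n) {
  if (n == 0) return(numeric(0))
  xi <- (seq_len(n) - 0.5) / n
  0.5 * (1 + cos(pi * xi))
}

#' Wave-optics detector image
#'
#' Full wave simulation of one exposure: exit field (object x mask) ->
#' angular-spectrum propagation over `z` -> intensity -> Gaussian source
#' blur at the detector plane -> pixel binning (x-integral over each pixel
#' footprint, mean over rows), yielding the same length-unit images as the
#' transport-model forward operators (an empty beam gives `we` per pixel).
#'
#' A guard band of `guard_periods` mask periods is added on each side: the
#' object deviation from empty beam is edge-replicated and cosine-tapered to
#' zero across the guard so the periodic FFT wrap-around sees an empty beam
#' on both ends; the guard is cropped before binning.
#'
#' @param obj A `projected_object`.
#' @param spec A `mask_spec` (binary masks are evaluated exactly).
#' @param geometry An [imaging_geometry()]; `nx` must be even (whole number
#'   of mask periods) and `s >= 32` (>= 64 samples per period).
#' @param source_fwhm Projected source FWHM at the detector plane (m); 0
#'   disables the blur. Default 7 microns (a microfocus tube spot).
#' @param guard_periods Guard-band width in mask periods per side.
#' @return A `detector_image` of kind `"wave"`.
#' @export
wave_image <- function(obj, spec, geometry, source_fwhm = 7e-6,
                       guard_periods = 8L) {
  stopifnot(inherits(obj, "projected_object"), inherits(spec, "mask_spec"),
            inherits(geometry, "imaging_geometry"))
  if (geometry$nx %% 2 != 0) {
    stop("wave_image needs an even number of pixel columns (whole mask periods)")
  }
  if (geometry$s < 32) {
    warning("oversampling < 32 per pixel (< 64 per mask period): wave simulation under-resolves the mask")
  }
  s <- geometry$s
  dx <- geometry$p / s
  g <- 2L * as.integer(guard_periods)       # guard width in pixels per side
  gn <- g * s                               # ... in fine columns
  nxf <- geometry$nx * s

  # extended fine x axis; mask continues periodically across the guard
  x_ext <- (seq_len(nxf + 2 * gn) - 0.5 - gn) * dx
  w <- rev(guard_taper(gn))                 # 0 at outer edge -> 1 inner
  Tl <- 1 + outer(obj$T[, 1] - 1, w)        # left guard: taper T to 1
  Tr <- 1 + outer(obj$T[, nxf] - 1, rev(w))
  Pl <- outer(obj$phi[, 1], w)
  Pr <- outer(obj$phi[, nxf], rev(w))
  Text <- cbind(Tl, obj$T, Tr)
  Pext <- cbind(Pl, obj$phi, Pr)
  obj_ext <- new_projected_object(Text, Pext, dx, obj$dy, geometry)

  U0 <- object_exit_field(obj_ext, spec, x = x_ext)
  Uz <- angular_spectrum(U0, geometry$lambda, geometry$z)
  I <- Mod(Uz$values)^2

  if (source_fwhm > 0) {
    sigma <- source_fwhm / (2 * sqrt(2 * log(2)))
    n <- ncol(I)
    f <- (((seq_len(n) - 1) + floor(n / 2)) %% n - floor(n / 2)) / (n * dx)
    mtf <- exp(-2 * pi^2 * sigma^2 * f^2)
    Ispec <- t(stats::mvfft(t(I + 0i)))
    I <- Re(t(stats::mvfft(t(sweep(Ispec, 2, mtf, `*`)), inverse = TRUE)) / n)
  }

  I <- I[, (gn + 1):(gn + nxf), drop = FALSE]
  vals <- pixel_average(I, geometry) * geometry$p
  new_detector_image(vals, geometry$p, "wave",
                     meta = list(we = effective_aperture(spec),
                                 alpha = mask_contrast(spec), parity = 1,
                                 source_fwhm = source_fwhm,
                                 guard_periods = guard_periods))
}
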