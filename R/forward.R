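# Transport-of-intensity forward models.
#
# Pixel-level model: with an aligned mask of period 2p, the intensity
# collected by pixel n reduces to
#
#   In = we * Tn * (1 - Ln) + parity * (-1)^n * alpha * Tn * Dn
#
# where Tn is the pixel-averaged transmission, Ln = (z/k) lap(phi) the
# propagation-based (Laplacian) term, Dn = (z/k) d(phi)/dx the beamlet
# displacement, we the effective aperture and alpha the mask contrast.
# With parity = +1 (default) the index origin puts a slit centre at x = 0,
# so a positive Dn brightens even columns; parity = -1 is the same model
# with the index origin shifted by one pixel. Pre-flat-correction images
# carry units of length (metres) so that flat-field correction is exactly
# dimensionless.

new_detector_image <- function(values, p, kind, meta = list()) {
  stopifnot(is.matrix(values), is.numeric(p), p > 0)
  if (!all(is.finite(values))) stop("detector image values must be finite")
  structure(list(values = values, p = p, kind = kind, meta = meta),
            class = "detector_image")
}

#' Detector image container
#'
#' @param values Matrix of per-pixel intensities, shape `(ny, nx)`.
#' @param p Pixel size (m).
#' @param kind One of `"sample_mask"`, `"flat"`, `"pb"`, `"wave"`.
#' @param meta Provenance list (mask coefficients, parity, geometry, seed).
#' @return A `detector_image`.
#' @export
detector_image <- function(values, p, kind = "sample_mask", meta = list()) {
  new_detector_image(values, p, kind, meta)
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> %s, %d x %d px (p = %g um), values in [%.4g, %.4g]\n",
              x$kind, nrow(x$values), ncol(x$values), x$p * 1e6,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Free-space propagated intensity (mask-free propagation-based model)
#'
#' Linearised intensity transport over distance z on the fine grid:
#' with the cross term, `I = T - (z/k) (grad T . grad phi + T lap phi)`;
#' without it (soft-object approximation),
#' `I = T (1 - (z/k) lap phi)`.
#'
#' @param obj A `projected_object`.
#' @param geometry An [imaging_geometry()].
#' @param keep_cross_term Keep the `grad I . grad phi` term.
#' @param clip Clip negative intensities to zero (otherwise only warn).
#' @return Fine-grid intensity matrix (dimensionless, contact image = T).
#' @export
tie_propagate <- function(obj, geometry, keep_cross_term = TRUE, clip = FALSE) {
  stopifnot(inherits(obj, "projected_object"),
            inherits(geometry, "imaging_geometry"))
  zk <- geometry$z / geometry$k
  lap <- phase_laplacian(obj)
  if (keep_cross_term) {
    tx <- deriv_x(obj$T, obj$dx)
    ty <- deriv_y(obj$T, obj$dy)
    px <- deriv_x(obj$phi, obj$dx)
    py <- deriv_y(obj$phi, obj$dy)
    out <- obj$T - zk * (tx * px + ty * py + obj$T * lap)
  } else {
    out <- obj$T * (1 - zk * lap)
  }
  if (any(out < 0)) {
    warning("negative propagated intensities: outside the validity regime of the linearised transport model")
    if (clip) out[out < 0] <- 0
  }
  out
}

#' Pixel-level fields Tn, Ln, Dn
#'
#' Pixel averages of the transmission, of `(z/k) lap(phi)` and of
#' `(z/k) d(phi)/dx`. `Dn` has units of length: it is the lateral beamlet
#' displacement at the detector (propagation distance times refraction
#' angle).
#'
#' @param obj A `projected_object` on the geometry's fine grid.
#' @param geometry An [imaging_geometry()].
#' @return An object of class `pixel_fields` with matrices `Tn`, `Ln`, `Dn`
#'   of shape `(ny, nx)`.
#' @export
compute_pixel_fields <- function(obj, geometry) {
  zk <- geometry$z / geometry$k
  structure(
    list(
      Tn = pixel_average(obj$T, geometry),
      Ln = zk * pixel_average(phase_laplacian(obj), geometry),
      Dn = zk * pixel_average(phase_gradient(obj), geometry),
      geometry = geometry
    ),
    class = "pixel_fields"
  )
}

#' @export
print.pixel_fields <- function(x, ...) {
  cat(sprintf("<pixel_fields> %d x %d px; Tn in [%.4g, %.4g], |Ln| <= %.3g, |Dn| <= %.3g m\n",
              nrow(x$Tn), ncol(x$Tn), min(x$Tn), max(x$Tn),
              max(abs(x$Ln)), max(abs(x$Dn))))
  invisible(x)
}

fringe_signs <- function(nx, parity = 1) {
  if (!parity %in% c(1, -1)) stop("parity must be +1 or -1")
  parity * rep_len(c(1, -1), nx)
}

#' Closed-form single-mask image
#'
#' The two-coefficient pixel model
#' `In = we Tn (1 - Ln) + parity (-1)^n alpha Tn Dn`. The whole mask enters
#' only through `we` and `alpha`; the alternating factor produces the
#' characteristic bright/dark fringes wherever the phase gradient is
#' non-zero.
#'
#' @param fields A `pixel_fields` from [compute_pixel_fields()].
#' @param coeffs A [mask_coefficients()].
#' @param parity +1 (default: slit centre at x = 0, positive `Dn` brightens
#'   even columns) or -1 (index origin shifted by one pixel; the
#'   conventional minus-sign form of the model).
#' @return A `detector_image` (units of length, kind `"sample_mask"`).
#' @export
single_mask_image_closed_form <- function(fields, coeffs, parity = 1) {
  stopifnot(inherits(fields, "pixel_fields"), inherits(coeffs, "mask_coefficients"))
  if (coeffs$we <= 0) stop("effective aperture we must be positive")
  nx <- ncol(fields$Tn)
  sgn <- matrix(fringe_signs(nx, parity), nrow = nrow(fields$Tn), ncol = nx,
                byrow = TRUE)
  vals <- coeffs$we * fields$Tn * (1 - fields$Ln) +
    coeffs$alpha * sgn * fields$Tn * fields$Dn
  if (any(vals < 0)) {
    warning("negative closed-form intensities (|alpha Tn Dn| exceeds we Tn (1 - Ln)): refraction too strong for the linearised model")
  }
  new_detector_image(vals, fields$geometry$p, "sample_mask",
                     meta = list(we = coeffs$we, alpha = coeffs$alpha,
                                 parity = parity))
}

#' Pixel-integrated single-mask image
#'
#' Direct numeric form of the masked transport model: per pixel,
#' `In = int T M dx - (z/k) int T (dM/dx) (dphi/dx) dx - (z/k) int T M lap(phi) dx`,
#' integrated on the fine grid with the analytic series derivative of the
#' mask. This is the oracle the closed form is checked against; the two
#' agree up to the slow-variation (within-pixel constancy) assumption.
#'
#' @param obj A `projected_object`.
#' @param spec An aligned `mask_spec`.
#' @param geometry An [imaging_geometry()].
#' @return A `detector_image` (units of length).
#' @export
single_mask_image_integrated <- function(obj, spec, geometry) {
  stopifnot(inherits(obj, "projected_object"), inherits(spec, "mask_spec"),
            inherits(geometry, "imaging_geometry"))
  require_aligned(spec, "single_mask_image_integrated")
  if (identical(spec$type, "binary") && 2 * geometry$s < 64) {
    warning("fewer than 64 fine samples per mask period: binary mask transitions are under-resolved")
  }
  ax <- fine_axes(geometry)
  M <- mask_transmission(spec, ax$x)
  dM <- mask_transmission_deriv(spec, ax$x)
  zk <- geometry$z / geometry$k
  px <- phase_gradient(obj)
  lap <- phase_laplacian(obj)
  integrand <- sweep(obj$T, 2, M, `*`) -
    zk * sweep(obj$T * px, 2, dM, `*`) -
    zk * sweep(obj$T * lap, 2, M, `*`)
  # x-integral over each pixel, mean over fine rows within each pixel row
  vals <- pixel_average(integrand, geometry) * geometry$p
  new_detector_image(vals, geometry$p, "sample_mask",
                     meta = list(we = effective_aperture(spec),
                                 alpha = mask_contrast(spec), parity = 1,
                                 model = "integrated"))
}

#' Flat-field (mask-only) image
#'
#' With no object, every pixel integrates the mask over one period's half:
#' a uniform image at the effective aperture `we`.
#'
#' @param coeffs A [mask_coefficients()] with `we > 0`.
#' @param geometry An [imaging_geometry()].
#' @return A `detector_image` of kind `"flat"`.
#' @export
flat_field_image <- function(coeffs, geometry) {
  stopifnot(inherits(coeffs, "mask_coefficients"))
  if (coeffs$we <= 0) stop("effective aperture we must be positive")
  new_detector_image(matrix(coeffs$we, geometry$ny, geometry$nx),
                     geometry$p, "flat",
                     meta = list(we = coeffs$we, alpha = coeffs$alpha))
}

#' Add Poisson counting noise to a detector image
#'
#' Scales the image so that the flat level `we` corresponds to
#' `mean_counts_flat` expected counts per pixel, draws Poisson counts, and
#' rescales back to the image's original units. Deterministic for a fixed
#' seed (the caller's RNG state is left untouched).
#'
#' @param image A `detector_image` with non-negative values.
#' @param mean_counts_flat Expected counts per pixel at the flat level.
#' @param seed Integer seed.
#' @param we Flat reference level; defaults to the image's `meta$we`.
#' @return A noisy `detector_image`.
#' @export
add_poisson_noise <- function(image, mean_counts_flat, seed, we = NULL) {
  stopifnot(inherits(image, "detector_image"))
  if (!all(is.finite(image$values))) stop("image has non-finite values")
  if (any(image$values < 0)) stop("Poisson noise requires non-negative intensities")
  if (!is.numeric(mean_counts_flat) || mean_counts_flat <= 0) {
    stop("mean_counts_flat must be positive")
  }
  we <- we %||% image$meta$we
  if (is.null(we) || we <= 0) stop("flat reference level we unknown; pass we explicitly")
  scale <- mean_counts_flat / we
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(image$values), lambda = image$values * scale)
  out <- image
  out$values <- matrix(counts / scale, nrow(image$values), ncol(image$values))
  out$meta$seed <- as.integer(seed)
  out$meta$mean_counts_flat <- mean_counts_flat
  out
}

#' Propagation-based pixel image
#'
#' The mask-free pixel-level signal `Tn (1 - Ln)`: attenuation combined
#' with Laplacian-phase edge enhancement. This is what the single-mask
#' model reduces to (times `we`) for a structureless plate, and what the
#' pair-sum retrieval channel estimates.
#'
#' @param fields A `pixel_fields`.
#' @return Matrix `(ny, nx)`, dimensionless.
#' @export
pb_pixel_image <- function(fields) {
  stopifnot(inherits(fields, "pixel_fields"))
  fields$Tn * (1 - fields$Ln)
}
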