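# Fourier-series model of the periodic absorption mask.
#
# The mask transmission is M(x) = sum_m Cm cos(2 pi m x / (2 p)): a cosine
# series with period exactly twice the detector pixel size, evaluated at
# x - offset. Slit (transparent) centres sit at even pixel boundaries
# x = 2 j p when offset = 0. Everything the mask does to the pixel-level
# image model reduces to two numbers: the effective aperture we = C0 p and
# the mask contrast alpha = 2 sum_odd Cm.

# allowed excursion of the sampled series outside [0, 1]: a truncated series
# for a discontinuous (binary) profile overshoots by ~9% of the jump (Gibbs)
mask_ripple_allowance <- function(type, contrast = 1) {
  if (identical(type, "binary")) 0.12 * contrast else 1e-9
}

new_mask_spec <- function(p, coeffs, offset = 0, type = "series",
                          open_fraction = NA_real_, contrast = NA_real_) {
  stopifnot(is.numeric(p), length(p) == 1, p > 0)
  stopifnot(is.numeric(coeffs), length(coeffs) >= 1, all(is.finite(coeffs)))
  spec <- structure(
    list(p = p, coeffs = as.numeric(coeffs), offset = offset, type = type,
         open_fraction = open_fraction, contrast = contrast),
    class = "mask_spec"
  )
  # dense physical-range check over one period (4096 points)
  xs <- seq(0, 2 * p, length.out = 4097)[-4097]
  m <- mask_transmission(spec, xs + offset)
  tol <- mask_ripple_allowance(type, if (is.na(contrast)) 1 else contrast)
  if (min(m) < -tol || max(m) > 1 + tol) {
    stop(sprintf("mask transmission outside [0, 1] (range [%.4g, %.4g], allowance %.3g)",
                 min(m), max(m), tol))
  }
  c0 <- coeffs[1]
  if (c0 < 0 || c0 > 1) stop("C0 (mean transmission) must lie in [0, 1]")
  spec
}

#' @export
print.mask_spec <- function(x, ...) {
  cat(sprintf(
    "<mask_spec> type = %s, period = %g um (2p), %d harmonics, offset = %g m; we = %.4g um, alpha = %.4g\n",
    x$type, 2 * x$p * 1e6, length(x$coeffs) - 1L, x$offset,
    effective_aperture(x) * 1e6, mask_contrast(x)))
  invisible(x)
}

#' Binary (square-wave) mask
#'
#' An idealised strip mask: transparent slit of width `open_fraction * 2p`
#' centred at x = 0 (i.e. at every other pixel boundary), blocked region
#' transmitting `1 - contrast`. Represented by its truncated Fourier series;
#' the exact square-wave profile is retained for exact evaluation (used by
#' the wave-optics simulator, which cannot take the square root of a Gibbs
#' undershoot).
#'
#' Closed-form coefficients: `C0 = 1 - contrast (1 - open_fraction)`,
#' `Cm = contrast * (2 / (m pi)) sin(m pi open_fraction)` for m >= 1.
#'
#' @param open_fraction Transparent fraction of the period, in (0, 1).
#' @param contrast Transmission drop of the blocked strips, in (0, 1].
#' @param p Detector pixel size (m); the mask period is `2 p`.
#' @param n_harmonics Series truncation order (>= 32).
#' @return A `mask_spec`.
#' @export
#' @examples
#' m1 <- binary_mask(0.5, 1, 55e-6)
#' effective_aperture(m1) # p / 2
binary_mask <- function(open_fraction, contrast, p, n_harmonics = 256L) {
  if (!is.numeric(open_fraction) || open_fraction <= 0 || open_fraction >= 1) {
    stop("open_fraction must lie strictly inside (0, 1)")
  }
  if (!is.numeric(contrast) || contrast <= 0 || contrast > 1) {
    stop("contrast must lie in (0, 1]")
  }
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 32L) stop("n_harmonics must be >= 32 (truncation quality)")
  m <- seq_len(n_harmonics)
  coeffs <- c(1 - contrast * (1 - open_fraction),
              contrast * (2 / (m * pi)) * sin(m * pi * open_fraction))
  new_mask_spec(p, coeffs, offset = 0, type = "binary",
                open_fraction = open_fraction, contrast = contrast)
}

#' Cosine mask
#'
#' The smooth two-coefficient mask `M(x) = 0.5 + 0.5 cos(pi x / p)`:
#' `C0 = C1 = 1/2`, all higher harmonics zero. Fully transparent at slit
#' centres (x = 0 mod 2p) and fully blocking at strip centres (x = p mod 2p).
#'
#' @param p Detector pixel size (m).
#' @return A `mask_spec`.
#' @export
cosine_mask <- function(p) {
  new_mask_spec(p, c(0.5, 0.5), offset = 0, type = "cosine")
}

#' Mask from explicit Fourier coefficients
#'
#' @param p Detector pixel size (m).
#' @param coeffs Numeric vector `(C0, C1, ...)`.
#' @param offset Alignment shift x0 (m); the series is evaluated at
#'   `x - offset`. Only offset-0 (aligned) masks admit the closed-form
#'   pixel-level model.
#' @return A `mask_spec`.
#' @export
mask_from_coeffs <- function(p, coeffs, offset = 0) {
  new_mask_spec(p, coeffs, offset = offset, type = "series")
}

#' Evaluate the mask transmission
#'
#' Evaluates the (truncated) Fourier series at `x - offset`; periodic with
#' period `2 p`. With `exact = TRUE`, binary masks are evaluated as the
#' ideal square wave instead of the truncated series (no Gibbs ripple).
#'
#' @param spec A `mask_spec`.
#' @param x Positions in metres (vectorised).
#' @param exact Use the exact profile where one exists.
#' @return Transmission values.
#' @export
mask_transmission <- function(spec, x, exact = FALSE) {
  stopifnot(inherits(spec, "mask_spec") || is.list(spec))
  xr <- x - spec$offset
  if (exact && identical(spec$type, "binary")) {
    # centre each point into (-p, p]; slit is |xc| < open_fraction * p
    xc <- ((xr + spec$p) %% (2 * spec$p)) - spec$p
    inside <- abs(xc) < spec$open_fraction * spec$p
    return(ifelse(inside, 1, 1 - spec$contrast))
  }
  m <- seq_along(spec$coeffs) - 1
  # outer(x, m) can be large; fine at the sizes used here
  drop(cos(outer(xr, m) * (pi / spec$p)) %*% spec$coeffs)
}

# analytic series derivative dM/dx (needed by the pixel-integrated model)
mask_transmission_deriv <- function(spec, x) {
  m <- seq_along(spec$coeffs) - 1
  xr <- x - spec$offset
  -drop(sin(outer(xr, m) * (pi / spec$p)) %*% (spec$coeffs * m)) * (pi / spec$p)
}

require_aligned <- function(spec, what) {
  if (!isTRUE(all.equal(spec$offset, 0))) {
    stop(what, " assumes an aligned mask (offset = 0); got offset = ", spec$offset)
  }
}

#' Numeric integral of the mask over one pixel
#'
#' Midpoint quadrature of `M(x)` over pixel `n`'s footprint
#' `[n p, (n+1) p]`. For any mask of period `2 p` this equals `C0 p` for
#' every pixel — the per-pixel transparent width.
#'
#' @param spec An aligned `mask_spec`.
#' @param n 0-based pixel index (vectorised).
#' @param n_points Quadrature points per pixel.
#' @return Integral value(s) in metres.
#' @export
pixel_mask_integral <- function(spec, n, n_points = 4096L) {
  require_aligned(spec, "pixel_mask_integral")
  dx <- spec$p / n_points
  vapply(n, function(ni) {
    xs <- ni * spec$p + (seq_len(n_points) - 0.5) * dx
    sum(mask_transmission(spec, xs)) * dx
  }, numeric(1))
}

#' Mask transmission difference across one pixel
#'
#' `M((n+1) p) - M(n p)`: the integral of `dM/dx` over pixel `n`. For an
#' aligned mask this equals `-2 sum_odd Cm * (-1)^n = -alpha (-1)^n`, the
#' alternating factor behind the differential-phase fringes.
#'
#' @param spec An aligned `mask_spec`.
#' @param n 0-based pixel index (vectorised).
#' @return Dimensionless difference(s).
#' @export
boundary_difference <- function(spec, n) {
  require_aligned(spec, "boundary_difference")
  mask_transmission(spec, (n + 1) * spec$p) - mask_transmission(spec, n * spec$p)
}

#' Effective aperture of a mask
#'
#' `we = C0 p`: the mask transmission integrated over one pixel, i.e. the
#' effective transparent width. Scales the propagation-based part of the
#' pixel signal.
#'
#' @param spec A `mask_spec`.
#' @return Length in metres.
#' @export
effective_aperture <- function(spec) {
  spec$coeffs[1] * spec$p
}

#' Mask contrast
#'
#' `alpha = 2 sum_m C_{2m+1}`: twice the sum of the odd Fourier
#' coefficients, equal to the transmission difference between slit centre
#' and strip centre for an aligned mask. Scales the differential-phase part
#' of the pixel signal.
#'
#' @param spec A `mask_spec`.
#' @return Dimensionless contrast.
#' @export
mask_contrast <- function(spec) {
  cm <- spec$coeffs[-1]
  if (length(cm) == 0) return(0)
  odd <- seq(1, length(cm), by = 2) # harmonic orders 1, 3, 5, ...
  2 * sum(cm[odd])
}

#' Mask coefficient pair (we, alpha)
#'
#' The two numbers that fully determine an aligned mask's effect in the
#' pixel-level model.
#'
#' @param spec A `mask_spec`, or `NULL` to supply `we`/`alpha` directly.
#' @param we,alpha Direct values (used when `spec` is NULL).
#' @return An object of class `mask_coefficients` with fields `we`, `alpha`.
#' @export
mask_coefficients <- function(spec = NULL, we = NULL, alpha = NULL) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "mask_spec"))
    require_aligned(spec, "mask_coefficients")
    we <- effective_aperture(spec)
    alpha <- mask_contrast(spec)
  }
  stopifnot(is.numeric(we), length(we) == 1, is.numeric(alpha), length(alpha) == 1)
  if (we < 0) stop("effective aperture we must be >= 0")
  structure(list(we = we, alpha = alpha), class = "mask_coefficients")
}

#' @export
print.mask_coefficients <- function(x, ...) {
  cat(sprintf("<mask_coefficients> we = %.4g um, alpha = %.4g\n",
              x$we * 1e6, x$alpha))
  invisible(x)
}

#' Serialise a mask to a config list
#'
#' @param spec A `mask_spec`.
#' @return A plain list suitable for `yaml::write_yaml()`.
#' @export
mask_to_config <- function(spec) {
  stopifnot(inherits(spec, "mask_spec"))
  out <- list(type = spec$type, pixel_size = sprintf("%.12g m", spec$p),
              offset = sprintf("%.12g m", spec$offset))
  if (identical(spec$type, "binary")) {
    out$open_fraction <- spec$open_fraction
    out$contrast <- spec$contrast
    out$harmonics <- length(spec$coeffs) - 1L
  } else if (identical(spec$type, "series")) {
    out$coeffs <- spec$coeffs
  }
  out
}

#' Build a mask from a config list
#'
#' Accepts the blocks written by [mask_to_config()] (and used in run
#' configs): `type` is one of `"cosine"`, `"binary"`, `"series"`.
#'
#' @param cfg A named list.
#' @param p Fallback pixel size (m) when the block carries none.
#' @return A `mask_spec`.
#' @export
mask_from_config <- function(cfg, p = NULL) {
  if (is.null(cfg$type)) stop("mask config needs a 'type'")
  pm <- if (!is.null(cfg$pixel_size)) parse_quantity(cfg$pixel_size, "m") else p
  if (is.null(pm)) stop("mask config needs a pixel size")
  offset <- if (!is.null(cfg$offset)) parse_quantity(cfg$offset, "m") else 0
  spec <- switch(cfg$type,
    cosine = cosine_mask(pm),
    binary = binary_mask(cfg$open_fraction %||% 0.5, cfg$contrast %||% 1, pm,
                         cfg$harmonics %||% 256L),
    series = mask_from_coeffs(pm, unlist(cfg$coeffs)),
    stop("unknown mask type '", cfg$type, "'")
  )
  spec$offset <- offset
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
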