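# Single-shot retrieval: separate the propagation-based and
# differential-phase channels from one sample+mask image and one flat.
#
# After flat-field correction, adjacent columns in a row read
#   I_n     = A_n + parity (-1)^n (alpha / we) T_n D_n
#   I_{n+1} = A_{n+1} - parity (-1)^n (alpha / we) T_{n+1} D_{n+1}
# with A = Tn (1 - Ln). The half-sum estimates A; the half-difference,
# normalised by the sum and rescaled by we / alpha, estimates D. Dividing
# the pair difference by the pair sum is what fixes the we/alpha (rather
# than alpha/we) factor in the displacement formula.

#' Flat-field correction
#'
#' Element-wise ratio of the sample+mask image to the mask-only (flat)
#' image. Pixels whose flat value is at or below `epsilon * median(flat)`
#' are masked out (NA) and excluded from pairing downstream.
#'
#' @param sample,flat `detector_image`s of identical shape.
#' @param epsilon Relative positivity floor for the flat.
#' @return An object of class `corrected_image` (dimensionless values;
#'   carries the forward parity from the sample's metadata).
#' @export
flat_correct <- function(sample, flat, epsilon = 1e-6) {
  stopifnot(inherits(sample, "detector_image"), inherits(flat, "detector_image"))
  if (!all(dim(sample$values) == dim(flat$values))) {
    stop("sample and flat images have different shapes")
  }
  med <- stats::median(flat$values)
  bad <- !(flat$values > epsilon * med) | !is.finite(flat$values)
  if (all(bad)) stop("flat-field image is entirely at or below the positivity floor")
  vals <- sample$values / flat$values
  vals[bad] <- NA_real_
  structure(
    list(values = vals, p = sample$p,
         parity = sample$meta$parity %||% 1,
         meta = sample$meta),
    class = "corrected_image"
  )
}

#' @export
print.corrected_image <- function(x, ...) {
  cat(sprintf("<corrected_image> %d x %d px, parity %+d, values in [%.4g, %.4g] (%d masked)\n",
              nrow(x$values), ncol(x$values), x$parity,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' Pair-wise separation of PB and DPC channels
#'
#' For each column pair `(n, n+1)` in each row:
#' `pb = (I_n + I_{n+1}) / 2` (the propagation-based channel
#' `Tn (1 - Ln)`), and
#' `dpc = sign * (we / alpha) * (I_n - I_{n+1}) / (I_n + I_{n+1})` (the
#' beamlet displacement `Dn`, in metres), where `sign = parity * (-1)^n`.
#' `"disjoint"` pairing uses pairs `(0,1), (2,3), ...` — half-width output,
#' one value per slit, each assigned the pair-boundary coordinate
#' `(n+1) p`; `"sliding"` uses every adjacent pair — full-width output with
#' correlated neighbours.
#'
#' Pairs whose sum falls below `positivity_floor` (or containing masked
#' pixels) propagate as NA.
#'
#' @param corrected A `corrected_image` from [flat_correct()].
#' @param coeffs A [mask_coefficients()]; `alpha` must be non-zero for the
#'   displacement output to exist.
#' @param pairing `"disjoint"` (default) or `"sliding"`.
#' @param parity Override the fringe parity (default: taken from the
#'   corrected image).
#' @param positivity_floor Smallest admissible pair sum.
#' @return An object of class `retrieved_pair` with matrices `pb`
#'   (dimensionless) and `dpc` (metres), pair-centre coordinates `x`, and
#'   pairing metadata.
#' @export
retrieve_pb_dpc <- function(corrected, coeffs,
                            pairing = c("disjoint", "sliding"),
                            parity = NULL, positivity_floor = 1e-12) {
  stopifnot(inherits(corrected, "corrected_image"),
            inherits(coeffs, "mask_coefficients"))
  pairing <- match.arg(pairing)
  v <- corrected$values
  nx <- ncol(v)
  if (nx < 2) stop("need at least two pixel columns to form a pair")
  if (coeffs$alpha == 0) {
    stop("mask contrast alpha = 0: the differential-phase channel is undefined (uniform plate carries no fringes)")
  }
  parity <- parity %||% corrected$parity
  first <- switch(pairing,
                  disjoint = seq(1L, nx - 1L, by = 2L),
                  sliding  = seq_len(nx - 1L))
  a <- v[, first, drop = FALSE]
  b <- v[, first + 1L, drop = FALSE]
  sgn <- matrix(fringe_signs(nx, parity)[first], nrow = nrow(v),
                ncol = length(first), byrow = TRUE)
  s2 <- a + b
  ok <- is.finite(s2) & abs(s2) > positivity_floor
  pb <- s2 / 2
  dpc <- sgn * (coeffs$we / coeffs$alpha) * (a - b) / s2
  pb[!ok] <- NA_real_
  dpc[!ok] <- NA_real_
  structure(
    list(pb = pb, dpc = dpc,
         x = first * corrected$p,   # boundary between the two paired pixels
         pairing = pairing, parity = parity,
         we = coeffs$we, alpha = coeffs$alpha, p = corrected$p),
    class = "retrieved_pair"
  )
}

#' @export
print.retrieved_pair <- function(x, ...) {
  cat(sprintf("<retrieved_pair> %s pairing, %d x %d pairs; pb in [%.4g, %.4g], |dpc| <= %.3g m\n",
              x$pairing, nrow(x$pb), ncol(x$pb),
              min(x$pb, na.rm = TRUE), max(x$pb, na.rm = TRUE),
              max(abs(x$dpc), na.rm = TRUE)))
  invisible(x)
}

#' Refraction angle from retrieved displacement
#'
#' The beamlet displacement is propagation distance times refraction angle,
#' so `theta = dpc / z`.
#'
#' @param pair A `retrieved_pair`.
#' @param geometry An [imaging_geometry()] with `z > 0`.
#' @return Matrix of refraction angles (radians).
#' @export
dpc_to_refraction <- function(pair, geometry) {
  stopifnot(inherits(pair, "retrieved_pair"),
            inherits(geometry, "imaging_geometry"))
  if (geometry$z <= 0) stop("refraction angle needs a positive propagation distance")
  pair$dpc / geometry$z
}
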