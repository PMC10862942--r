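# Geometry, units and material constants shared by all modules.
# All lengths are in metres, energies in keV, phases in radians.

# hc in eV nm (CODATA); lambda[nm] = HC_EV_NM / E[eV]
HC_KEV_NM <- 1.239841984

#' X-ray wavelength from photon energy
#'
#' @param energy Photon energy in keV.
#' @return Wavelength in metres (`lambda = hc / E`).
#' @export
#' @examples
#' xray_wavelength(20) # ~6.2e-11 m
xray_wavelength <- function(energy) {
  stopifnot(is.numeric(energy), all(energy > 0))
  HC_KEV_NM / energy * 1e-9
}

#' X-ray wavenumber from photon energy
#'
#' @inheritParams xray_wavelength
#' @return Wavenumber `k = 2 pi / lambda` in 1/m.
#' @export
xray_wavenumber <- function(energy) {
  2 * pi / xray_wavelength(energy)
}

#' Imaging geometry
#'
#' Bundles the fixed system parameters: object-to-detector propagation
#' distance `z`, detector pixel size `p`, detector pixel counts `nx`, `ny`,
#' monochromatic design energy, and the oversampling factor `s` of the fine
#' computational grid (fine spacing `p / s`). The wavelength and wavenumber
#' are derived from the energy. The default values mirror a table-top
#' single-mask setup: 0.6 m propagation, 55 micron pixels, 20 keV design
#' energy (a monochromatic stand-in for a 40 kVp tube spectrum).
#'
#' The detector x axis is the mask-modulation direction. Pixel `n`
#' (0-based) occupies `[n p, (n+1) p)`; fine-grid samples sit at cell
#' centres `(i + 1/2) p / s`.
#'
#' @param z Object-to-detector distance in metres.
#' @param p Detector pixel size in metres.
#' @param nx,ny Detector pixel counts along x (mask modulation) and y.
#' @param energy Design photon energy in keV.
#' @param s Fine-grid oversampling factor (>= 8; >= 32 recommended when the
#'   geometry will be used with the wave-optics simulator).
#' @return An object of class `imaging_geometry`.
#' @export
#' @examples
#' g <- imaging_geometry(z = 0.6, p = 55e-6, nx = 64, ny = 8, energy = 20)
#' g$k * xray_wavelength(20) / (2 * pi) # 1
imaging_geometry <- function(z = 0.6, p = 55e-6, nx = 128L, ny = 8L,
                             energy = 20, s = 16L) {
  stopifnot(is.numeric(z), length(z) == 1, z >= 0)
  stopifnot(is.numeric(p), length(p) == 1, p > 0)
  stopifnot(nx >= 1, ny >= 1, energy > 0)
  s <- as.integer(s)
  if (s < 8L) {
    stop("oversampling factor s must be >= 8 (fine grid must resolve sub-pixel structure)")
  }
  lambda <- xray_wavelength(energy)
  structure(
    list(z = z, p = p, nx = as.integer(nx), ny = as.integer(ny),
         energy = energy, s = s, lambda = lambda, k = 2 * pi / lambda),
    class = "imaging_geometry"
  )
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat(sprintf(
    "<imaging_geometry> z = %g m, p = %g um, %d x %d px, E = %g keV (lambda = %.4g m), oversampling %d\n",
    x$z, x$p * 1e6, x$nx, x$ny, x$energy, x$lambda, x$s))
  invisible(x)
}

#' Fine-grid axes of a geometry
#'
#' @param geometry An [imaging_geometry()].
#' @return List with fine-grid cell-centre coordinates `x`, `y` (metres) and
#'   spacings `dx`, `dy`.
#' @export
fine_axes <- function(geometry) {
  stopifnot(inherits(geometry, "imaging_geometry"))
  dx <- geometry$p / geometry$s
  list(
    x = (seq_len(geometry$nx * geometry$s) - 0.5) * dx,
    y = (seq_len(geometry$ny * geometry$s) - 0.5) * dx,
    dx = dx, dy = dx
  )
}

#' Material optical constants
#'
#' A material is described by its refractive-index decrement `delta`
#' (n = 1 - delta + i beta) and linear attenuation coefficient `mu`, both at
#' the design energy.
#'
#' @param name Label.
#' @param delta Refractive-index decrement (dimensionless, >= 0).
#' @param mu Linear attenuation coefficient in 1/m (>= 0).
#' @return An object of class `xray_material`.
#' @export
xray_material <- function(name, delta, mu) {
  stopifnot(is.character(name), length(name) == 1)
  stopifnot(is.numeric(delta), length(delta) == 1, delta >= 0, is.finite(delta))
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0, is.finite(mu))
  structure(list(name = name, delta = delta, mu = mu), class = "xray_material")
}

#' @export
print.xray_material <- function(x, ...) {
  cat(sprintf("<xray_material> %s: delta = %.3g, mu = %.3g /m\n", x$name, x$delta, x$mu))
  invisible(x)
}

# Built-in constants at the 20 keV design energy.
# delta computed from electron density via r_e lambda^2 rho_e / (2 pi);
# mu from standard mass-attenuation tabulations times nominal density.
# Values are approximate (three significant figures) and config-overridable.
BUILTIN_MATERIALS <- list(
  pmma          = c(delta = 6.66e-7, mu = 68),
  water         = c(delta = 5.76e-7, mu = 81),
  polycarbonate = c(delta = 6.57e-7, mu = 65),
  air           = c(delta = 7.0e-10, mu = 0.094)
)

#' Built-in material table (20 keV)
#'
#' Returns optical constants for a small set of phantom materials at the
#' 20 keV design energy. `"plastic"` is an alias for polycarbonate.
#'
#' @param name One of `"pmma"`, `"water"`, `"polycarbonate"` (alias
#'   `"plastic"`), `"air"`.
#' @return An [xray_material()].
#' @export
#' @examples
#' builtin_material("pmma")
builtin_material <- function(name) {
  key <- tolower(name)
  if (key == "plastic") key <- "polycarbonate"
  if (!key %in% names(BUILTIN_MATERIALS)) {
    stop("unknown built-in material '", name, "'; known: ",
         paste(names(BUILTIN_MATERIALS), collapse = ", "),
         " (or construct one with xray_material())")
  }
  v <- BUILTIN_MATERIALS[[key]]
  xray_material(key, v[["delta"]], v[["mu"]])
}
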