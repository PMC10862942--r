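# Synthetic projection phantoms with analytic ground truth.
#
# A phantom is a pair of co-registered fine-grid fields: the intensity
# transmission T(x, y) in (0, 1] and the phase shift phi(x, y) in radians.
# Sign convention: X-ray phase is retarded (n = 1 - delta), so a projected
# thickness t gives phi = -k * delta * t <= 0. Flipping the convention flips
# only the sign of the retrieved differential-phase signal.

new_projected_object <- function(T, phi, dx, dy, geometry = NULL) {
  stopifnot(is.matrix(T), is.matrix(phi), all(dim(T) == dim(phi)))
  if (!all(is.finite(T)) || !all(is.finite(phi))) {
    stop("phantom fields must be finite")
  }
  if (any(T <= 0) || any(T > 1 + 1e-12)) {
    stop("transmission must lie in (0, 1]")
  }
  structure(list(T = T, phi = phi, dx = dx, dy = dy, geometry = geometry),
            class = "projected_object")
}

#' @export
print.projected_object <- function(x, ...) {
  cat(sprintf(
    "<projected_object> %d x %d fine grid (dx = %.3g m); T in [%.4g, %.4g], phi in [%.4g, %.4g] rad\n",
    nrow(x$T), ncol(x$T), x$dx, min(x$T), max(x$T), min(x$phi), max(x$phi)))
  invisible(x)
}

# chord length through a cylinder of radius r at lateral offset u
chord_length <- function(u, r) {
  t <- r * r - u * u
  2 * sqrt(pmax(t, 0))
}

#' Cylinder (rod) projection phantom
#'
#' Projects a solid cylinder with axis along y (parallel to the mask strips)
#' onto the fine grid: projected thickness `t(x) = 2 sqrt(R^2 - (x - c)^2)`
#' inside the rod, 0 outside; `T = exp(-mu t)`, `phi = -k delta t`.
#'
#' @param radius Cylinder radius in metres.
#' @param material An [xray_material()].
#' @param geometry An [imaging_geometry()].
#' @param center_x Axis position in metres (default: centre of the field of
#'   view).
#' @return A `projected_object`.
#' @export
#' @examples
#' g <- imaging_geometry(nx = 64, ny = 4, s = 8)
#' rod <- make_cylinder_phantom(1.5e-3, builtin_material("pmma"), g)
make_cylinder_phantom <- function(radius, material, geometry, center_x = NULL) {
  stopifnot(inherits(material, "xray_material"),
            inherits(geometry, "imaging_geometry"))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("radius must be a positive length")
  }
  ax <- fine_axes(geometry)
  fov <- geometry$nx * geometry$p
  if (is.null(center_x)) center_x <- fov / 2
  if (center_x - radius < 0 || center_x + radius > fov) {
    stop("cylinder does not fit in the field of view (radius too large or off-centre)")
  }
  t <- chord_length(ax$x - center_x, radius)
  nyf <- geometry$ny * geometry$s
  Tm <- matrix(exp(-material$mu * t), nrow = nyf, ncol = length(t), byrow = TRUE)
  ph <- matrix(-geometry$k * material$delta * t, nrow = nyf, ncol = length(t),
               byrow = TRUE)
  new_projected_object(Tm, ph, ax$dx, ax$dy, geometry)
}

#' Nested tube phantom (wall + fill + rod)
#'
#' A hollow cylinder (tube wall) filled with a liquid, containing a coaxial
#' solid rod; all axes along y. Per-material projected thicknesses follow
#' from nested-cylinder chord lengths, and attenuation/phase sum over
#' materials.
#'
#' @param outer_r Tube outer radius (m).
#' @param wall_thickness Tube wall thickness (m).
#' @param rod_r Rod radius (m); must satisfy `rod_r < outer_r - wall_thickness`.
#' @param wall_mat,fill_mat,rod_mat [xray_material()]s.
#' @param geometry An [imaging_geometry()].
#' @param center_x Common axis position (default FOV centre).
#' @return A `projected_object`.
#' @export
make_tube_phantom <- function(outer_r, wall_thickness, rod_r,
                              wall_mat, fill_mat, rod_mat,
                              geometry, center_x = NULL) {
  stopifnot(inherits(geometry, "imaging_geometry"))
  if (outer_r <= 0 || wall_thickness <= 0 || rod_r <= 0) {
    stop("all radii/thicknesses must be positive")
  }
  inner_r <- outer_r - wall_thickness
  if (inner_r <= 0) stop("wall thicker than tube radius")
  if (rod_r >= inner_r) {
    stop("rod does not fit inside the tube bore (rod_r >= outer_r - wall_thickness)")
  }
  for (m in list(wall_mat, fill_mat, rod_mat)) {
    stopifnot(inherits(m, "xray_material"))
  }
  ax <- fine_axes(geometry)
  fov <- geometry$nx * geometry$p
  if (is.null(center_x)) center_x <- fov / 2
  if (center_x - outer_r < 0 || center_x + outer_r > fov) {
    stop("tube does not fit in the field of view")
  }
  u <- ax$x - center_x
  t_outer <- chord_length(u, outer_r)
  t_inner <- chord_length(u, inner_r)
  t_rod <- chord_length(u, rod_r)
  t_wall <- t_outer - t_inner
  t_fill <- t_inner - t_rod
  mut <- wall_mat$mu * t_wall + fill_mat$mu * t_fill + rod_mat$mu * t_rod
  dt <- wall_mat$delta * t_wall + fill_mat$delta * t_fill + rod_mat$delta * t_rod
  nyf <- geometry$ny * geometry$s
  Tm <- matrix(exp(-mut), nrow = nyf, ncol = length(u), byrow = TRUE)
  ph <- matrix(-geometry$k * dt, nrow = nyf, ncol = length(u), byrow = TRUE)
  new_projected_object(Tm, ph, ax$dx, ax$dy, geometry)
}

#' Smooth Gaussian phantom
#'
#' A band-limited test object: `phi = -amplitude_phi * G`,
#' `T = 1 - amplitude_att * G`, with `G` a unit-peak 2-D Gaussian of width
#' `sigma`. Used to probe the slow-variation assumption of the pixel-level
#' model: the model holds when features are much wider than a pixel, so
#' `sigma < 4 p` triggers a warning.
#'
#' @param amplitude_phi Peak magnitude of the (negative) phase shift, radians.
#' @param amplitude_att Peak attenuation depth, in `[0, 1)`.
#' @param sigma Gaussian width in metres.
#' @param geometry An [imaging_geometry()].
#' @param center_x,center_y Peak position (default FOV centre).
#' @return A `projected_object`.
#' @export
make_gaussian_phantom <- function(amplitude_phi, amplitude_att, sigma, geometry,
                                  center_x = NULL, center_y = NULL) {
  stopifnot(inherits(geometry, "imaging_geometry"))
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (amplitude_att < 0 || amplitude_att >= 1) {
    stop("amplitude_att must be in [0, 1)")
  }
  if (sigma < 4 * geometry$p) {
    warning("sigma < 4 pixels: the slow-variation assumption of the pixel-level model is violated")
  }
  ax <- fine_axes(geometry)
  if (is.null(center_x)) center_x <- geometry$nx * geometry$p / 2
  if (is.null(center_y)) center_y <- geometry$ny * geometry$p / 2
  gx <- exp(-(ax$x - center_x)^2 / (2 * sigma^2))
  gy <- exp(-(ax$y - center_y)^2 / (2 * sigma^2))
  G <- outer(gy, gx)
  new_projected_object(1 - amplitude_att * G, -amplitude_phi * G,
                       ax$dx, ax$dy, geometry)
}

# first derivative along x (columns): central differences, one-sided at edges
deriv_x <- function(f, dx) {
  n <- ncol(f)
  if (n < 3) stop("need at least 3 samples along x for finite differences")
  d <- f
  d[, 2:(n - 1)] <- (f[, 3:n] - f[, 1:(n - 2)]) / (2 * dx)
  d[, 1] <- (f[, 2] - f[, 1]) / dx
  d[, n] <- (f[, n] - f[, n - 1]) / dx
  d
}

deriv_y <- function(f, dy) t(deriv_x(t(f), dy))

# second derivative along x; one-sided (shifted 3-point) stencil at edges
second_deriv_x <- function(f, dx) {
  n <- ncol(f)
  if (n < 3) stop("need at least 3 samples along x for finite differences")
  d <- f
  d[, 2:(n - 1)] <- (f[, 3:n] - 2 * f[, 2:(n - 1)] + f[, 1:(n - 2)]) / dx^2
  d[, 1] <- (f[, 3] - 2 * f[, 2] + f[, 1]) / dx^2
  d[, n] <- (f[, n] - 2 * f[, n - 1] + f[, n - 2]) / dx^2
  d
}

#' Transverse phase gradient of a phantom
#'
#' Central finite differences of `phi` along x on the fine grid (one-sided
#' at the boundary columns). This is the quantity that drives the
#' differential-phase fringes: the beamlet displacement at the detector is
#' `D = (z / k) d(phi)/dx`, i.e. propagation distance times refraction angle.
#'
#' @param obj A `projected_object`.
#' @return Matrix of `d(phi)/dx` in rad/m on the fine grid.
#' @export
phase_gradient <- function(obj) {
  stopifnot(inherits(obj, "projected_object"))
  deriv_x(obj$phi, obj$dx)
}

#' Transverse phase Laplacian of a phantom
#'
#' Five-point stencil for `d2/dx2 + d2/dy2` of `phi` on the fine grid
#' (shifted stencils at boundaries). Drives the propagation-based
#' edge-enhancement term `L = (z / k) lap(phi)`.
#'
#' @param obj A `projected_object`.
#' @return Matrix of `lap(phi)` in rad/m^2.
#' @export
phase_laplacian <- function(obj) {
  stopifnot(inherits(obj, "projected_object"))
  second_deriv_x(obj$phi, obj$dx) + t(second_deriv_x(t(obj$phi), obj$dy))
}

#' Area-weighted pixel average of a fine-grid field
#'
#' Averages a fine-grid field over each detector pixel footprint (`s x s`
#' fine cells per pixel). Exact for the midpoint-sampled fine grid; preserves
#' the global mean.
#'
#' @param field Matrix of shape `(ny * s, nx * s)`.
#' @param geometry The [imaging_geometry()] defining `nx`, `ny`, `s`.
#' @return Matrix of per-pixel means, shape `(ny, nx)`.
#' @export
pixel_average <- function(field, geometry) {
  stopifnot(inherits(geometry, "imaging_geometry"), is.matrix(field))
  s <- geometry$s
  if (nrow(field) != geometry$ny * s || ncol(field) != geometry$nx * s) {
    stop(sprintf("field shape (%d, %d) is not commensurate with %d x %d pixels at oversampling %d",
                 nrow(field), ncol(field), geometry$ny, geometry$nx, s))
  }
  rows <- rowsum(field, rep(seq_len(geometry$ny), each = s), reorder = FALSE) / s
  out <- t(rowsum(t(rows), rep(seq_len(geometry$nx), each = s), reorder = FALSE)) / s
  dimnames(out) <- NULL
  out
}
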