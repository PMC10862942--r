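# Shared fixtures: small geometries and phantoms built in code.

ref_geometry <- function(nx = 128L, ny = 4L, s = 16L, z = 0.6, energy = 20) {
  imaging_geometry(z = z, p = 55e-6, nx = nx, ny = ny, energy = energy, s = s)
}

# phantom with spatially uniform attenuation and no phase: a Gaussian of
# essentially infinite width (flat to ~1e-12 across any test FOV)
uniform_phantom <- function(geometry, transmission = 1) {
  make_gaussian_phantom(0, 1 - transmission, sigma = 1e3, geometry = geometry)
}

# brute-force line integral of a disc indicator: thickness of a cylinder of
# radius r at lateral offset u, by rasterising the chord in z
raster_chord <- function(u, r, nz = 2e5) {
  dz <- 2 * r / nz
  zc <- (seq_len(nz) - 0.5) * dz - r
  vapply(u, function(ui) sum(ui^2 + zc^2 < r^2) * dz, numeric(1))
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  s <- if (is.null(scale)) max(abs(expected)) else scale
  expect_lt(max(abs(actual - expected)) / s, tol)
}
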