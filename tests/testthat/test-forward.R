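# TIE forward models: free-space, pixel fields, closed form vs direct
# pixel integration, flat fields, Poisson noise.

make_fields <- function(Tn, Ln, Dn, geometry) {
  structure(list(Tn = Tn, Ln = Ln, Dn = Dn, geometry = geometry),
            class = "pixel_fields")
}

test_that("free-space propagation reduces to the contact image", {
  g <- ref_geometry(nx = 32, ny = 4, s = 8)
  obj <- make_gaussian_phantom(0, 0.3, 8 * g$p, g)
  expect_equal(tie_propagate(obj, g), obj$T, tolerance = 1e-12)
  g0 <- ref_geometry(nx = 32, ny = 4, s = 8, z = 0)
  obj2 <- make_gaussian_phantom(2, 0.3, 8 * g0$p, g0)
  expect_equal(tie_propagate(obj2, g0), obj2$T, tolerance = 1e-12)
})

test_that("constant phase curvature gives a uniform intensity offset", {
  g <- ref_geometry(nx = 16, ny = 16, s = 8)
  ax <- fine_axes(g)
  obj <- make_gaussian_phantom(0, 0, 8 * g$p, g)
  c2 <- 5e7
  obj$phi <- c2 * (outer(rep(1, length(ax$y)), ax$x^2) +
                   outer(ax$y^2, rep(1, length(ax$x))))
  I <- tie_propagate(obj, g, keep_cross_term = TRUE)
  inner <- I[3:(nrow(I) - 2), 3:(ncol(I) - 2)]
  expect_rel_equal(inner, matrix(1 - 4 * c2 * g$z / g$k, nrow(inner), ncol(inner)),
                   tol = 1e-9)
})

test_that("pixel fields have the right trivial and symmetry structure", {
  g <- ref_geometry(nx = 64, ny = 2, s = 16)
  f0 <- compute_pixel_fields(empty_phantom(g), g)
  expect_true(all(f0$Tn == 1) && all(f0$Ln == 0) && all(f0$Dn == 0))
  # linear phase ramp: Dn = z g0 / k everywhere, Ln = 0
  ax <- fine_axes(g)
  obj <- empty_phantom(g)
  slope <- 2e4
  obj$phi <- matrix(rep(slope * ax$x, each = nrow(obj$phi)), nrow(obj$phi))
  f <- compute_pixel_fields(obj, g)
  expect_rel_equal(f$Dn, matrix(g$z * slope / g$k, g$ny, g$nx), tol = 1e-9)
  expect_lt(max(abs(f$Ln)), 1e-10)
  # centred cylinder: Dn antisymmetric about the axis
  rod <- make_cylinder_phantom(1e-3, builtin_material("pmma"), g)
  fr <- compute_pixel_fields(rod, g)
  expect_equal(fr$Dn[1, ], -rev(fr$Dn[1, ]), tolerance = 1e-10)
})

test_that("closed-form image obeys the two-coefficient pixel model", {
  g <- ref_geometry(nx = 8, ny = 2, s = 8)
  co <- mask_coefficients(cosine_mask(g$p))
  ones <- matrix(1, g$ny, g$nx); zeros <- matrix(0, g$ny, g$nx)
  # empty beam: uniform at we
  img <- single_mask_image_closed_form(make_fields(ones, zeros, zeros, g), co)
  expect_true(all(img$values == co$we))
  # uniform attenuation halves it
  img2 <- single_mask_image_closed_form(make_fields(0.5 * ones, zeros, zeros, g), co)
  expect_true(all(img2$values == 0.5 * co$we))
  # constant displacement: columns alternate we +/- alpha d
  d <- 3e-7
  img3 <- single_mask_image_closed_form(make_fields(ones, zeros, d + zeros, g),
                                        co, parity = 1)
  expect_equal(img3$values[1, ], co$we + co$alpha * d * (-1)^(0:(g$nx - 1)),
               tolerance = 1e-12)
  # parity flips the fringe sign, nothing else
  img4 <- single_mask_image_closed_form(make_fields(ones, zeros, d + zeros, g),
                                        co, parity = -1)
  expect_equal(img4$values + img3$values, matrix(2 * co$we, g$ny, g$nx),
               tolerance = 1e-12)
  # linear in Tn; fringe amplitude linear in Dn
  img5 <- single_mask_image_closed_form(make_fields(ones, zeros, 2 * d + zeros, g), co)
  expect_equal(img5$values - co$we, 2 * (img3$values - co$we), tolerance = 1e-12)
  expect_error(single_mask_image_closed_form(
    make_fields(ones, zeros, zeros, g), mask_coefficients(we = 0, alpha = 1)),
    "positive")
})

test_that("pixel-integrated image matches its trivial limits", {
  g <- ref_geometry(nx = 32, ny = 2, s = 32)
  mk <- cosine_mask(g$p)
  co <- mask_coefficients(mk)
  # empty beam: every pixel equals the pixel mask integral (= we)
  fi <- single_mask_image_integrated(empty_phantom(g), mk, g)
  expect_rel_equal(fi$values, matrix(co$we, g$ny, g$nx), tol = 1e-12)
  ff <- flat_field_image(co, g)
  expect_rel_equal(fi$values, ff$values, tol = 1e-12)
  # pure attenuation: phase terms vanish identically
  obj <- make_gaussian_phantom(0, 0.4, 8 * g$p, g)
  ia <- single_mask_image_integrated(obj, mk, g)
  # first term only: pixel average of T times M
  ax <- fine_axes(g)
  M <- mask_transmission(mk, ax$x)
  ref <- pixel_average(sweep(obj$T, 2, M, `*`), g) * g$p
  expect_equal(ia$values, ref, tolerance = 1e-14)
})

test_that("closed form agrees with pixel integration for slow phantoms", {
  errs <- vapply(c(8, 16), function(scale) {
    g <- ref_geometry(nx = 128, ny = 2, s = 32)
    mk <- cosine_mask(g$p)
    co <- mask_coefficients(mk)
    obj <- make_gaussian_phantom(20, 0, scale * g$p, g)
    cf <- single_mask_image_closed_form(compute_pixel_fields(obj, g), co, parity = 1)
    ii <- single_mask_image_integrated(obj, mk, g)
    max(abs(cf$values - ii$values)) / co$we
  }, numeric(1))
  expect_lt(errs[1], 1e-3)
  expect_gt(errs[1] / errs[2], 3) # roughly quadratic in p / feature scale
})

test_that("a structureless plate reduces the mask model to the PB model", {
  g <- ref_geometry(nx = 64, ny = 2, s = 16)
  plate <- mask_from_coeffs(g$p, 1) # we = p, alpha = 0
  obj <- make_gaussian_phantom(10, 0.2, 10 * g$p, g)
  masked <- single_mask_image_integrated(obj, plate, g)
  pb_fine <- tie_propagate(obj, g, keep_cross_term = FALSE)
  expect_equal(masked$values, g$p * pixel_average(pb_fine, g), tolerance = 1e-13)
  # closed form: p * Tn (1 - Ln) by construction
  f <- compute_pixel_fields(obj, g)
  cf <- single_mask_image_closed_form(f, mask_coefficients(plate))
  expect_equal(cf$values, g$p * pb_pixel_image(f), tolerance = 1e-14)
})

test_that("DPC component alternates sign and vanishes without phase gradient", {
  g <- ref_geometry(nx = 64, ny = 2, s = 16)
  co <- mask_coefficients(cosine_mask(g$p))
  obj <- make_gaussian_phantom(15, 0.05, 10 * g$p, g)
  f <- compute_pixel_fields(obj, g)
  img <- single_mask_image_closed_form(f, co, parity = 1)
  resid <- img$values - co$we * pb_pixel_image(f)
  sgn <- matrix((-1)^(0:(g$nx - 1)), g$ny, g$nx, byrow = TRUE)
  # demodulated residual has one sign wherever Dn is appreciable
  demod <- resid * sgn
  big <- abs(f$Dn) > 0.05 * max(abs(f$Dn))
  expect_true(all(demod[big] * sign(f$Dn[big]) > 0))
  # no phase gradient, no fringes: attenuation-only object has zero residual
  f2 <- compute_pixel_fields(make_gaussian_phantom(0, 0.3, 10 * g$p, g), g)
  img2 <- single_mask_image_closed_form(f2, co, parity = 1)
  expect_true(all(img2$values == co$we * pb_pixel_image(f2)))
})

test_that("flat field is uniform at we and linear in C0", {
  g <- ref_geometry(nx = 16, ny = 2, s = 8)
  co <- mask_coefficients(cosine_mask(g$p))
  ff <- flat_field_image(co, g)
  expect_equal(co$we, 27.5e-6, tolerance = 1e-12) # p / 2 for the cosine mask
  expect_true(all(ff$values == co$we))
  co2 <- mask_coefficients(we = 2 * co$we, alpha = co$alpha)
  expect_equal(flat_field_image(co2, g)$values, 2 * ff$values)
  expect_error(flat_field_image(mask_coefficients(we = 0, alpha = 0), g), "positive")
})

test_that("Poisson noise is seeded, unbiased and shrinks with counts", {
  g <- ref_geometry(nx = 32, ny = 8, s = 8)
  co <- mask_coefficients(cosine_mask(g$p))
  ff <- flat_field_image(co, g)
  n1 <- add_poisson_noise(ff, 1e4, seed = 42)
  n2 <- add_poisson_noise(ff, 1e4, seed = 42)
  expect_identical(n1$values, n2$values)
  expect_false(identical(add_poisson_noise(ff, 1e4, seed = 43)$values, n1$values))
  # high-count limit: relative noise ~ 1/sqrt(counts)
  hi <- add_poisson_noise(ff, 1e8, seed = 1)
  expect_lt(max(abs(hi$values - ff$values)) / co$we, 1e-3)
  # per-pixel variance ~ mean at the working count level
  reps <- vapply(1:200, function(s) add_poisson_noise(ff, 1e4, seed = s)$values[1, 1],
                 numeric(1))
  counts <- reps * 1e4 / co$we
  expect_equal(var(counts), 1e4, tolerance = 0.25)
  expect_error(add_poisson_noise(ff, -5, seed = 1), "positive")
  # caller RNG state is preserved
  set.seed(99); before <- .Random.seed
  invisible(add_poisson_noise(ff, 1e4, seed = 7))
  expect_identical(before, .Random.seed)
})
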