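test_that("HSC endpoints: identical contours give 1, displaced contours 0", {
  for (seed in c(1, 2)) {
    ph <- small_phantom(seed = seed)
    self <- hsc(ph, ph)
    expect_identical(self$value, 1)
    expect_equal(self$n_untouched, self$n_total_final)

    far <- translate_structure(ph, dx = 10)
    expect_identical(hsc(far, ph)$value, 0)
  }
})

test_that("HSC counts untouched slices exactly", {
  # 2 slices x 4 points; slice 1 untouched, slice 2 fully displaced
  fin <- contour_structure("fin", list(square_slice(2, z = 0),
                                       square_slice(2, z = 3)),
                           slice_thickness = 3)
  ini <- contour_structure("ini", list(square_slice(2, z = 0),
                                       square_slice(2, z = 3, x0 = 0.7)),
                           slice_thickness = 3)
  res <- hsc(ini, fin)
  expect_equal(res$n_total_final, 8L)
  expect_equal(res$n_untouched, 4L)
  expect_equal(res$value, 0.5)
})

test_that("sub-resolution offsets zero the exact HSC but not the adapted HSC", {
  ph <- small_phantom(seed = 4)
  off <- translate_structure(ph, dx = 0.2)
  expect_identical(hsc(off, ph)$value, 0)
  expect_identical(adapted_hsc(off, ph, clinical_tol = 0.5)$value, 1)

  off6 <- translate_structure(ph, dx = 0.6)
  expect_identical(adapted_hsc(off6, ph, clinical_tol = 0.5)$value, 0)
  expect_error(adapted_hsc(ph, ph, clinical_tol = 0), "> 0")
})

test_that("adapted HSC counts points within the clinical tolerance", {
  # alternate vertices displaced radially by 0.2 mm and 1.0 mm
  base <- ngon_slice(16, radius = 20)
  d <- rep(c(0.2, 1.0), 8)
  r <- 20 + d
  th <- 2 * pi * (0:15) / 16
  moved <- slice_contour(cbind(r * cos(th), r * sin(th)), z = 0)
  fin <- one_slice_structure(base, thickness = 3)
  ini <- one_slice_structure(moved, thickness = 3)
  expect_equal(adapted_hsc(ini, fin, clinical_tol = 0.5)$value, 0.5)
})

test_that("HSC is monotone in the matching tolerance", {
  ph <- small_phantom(seed = 9)
  jitter <- ph
  set.seed(42)
  jitter$slices <- lapply(jitter$slices, function(sl) {
    sl$xy <- sl$xy + matrix(stats::rnorm(length(sl$xy), sd = 0.3),
                            ncol = 2)
    sl
  })
  tols <- c(1e-6, 0.1, 0.3, 0.6, 1, 2)
  vals <- vapply(tols, function(t) hsc(jitter, ph, match_tol = t)$value,
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[length(vals)], 1)
})

test_that("HSC is asymmetric: denominator is always the final contour", {
  fine <- resample_contour(square_slice(2), 8)
  coarse <- square_slice(2)
  a <- one_slice_structure(fine, thickness = 3)    # 8 points on the square
  b <- one_slice_structure(coarse, thickness = 3)  # its 4 corners
  expect_equal(hsc(a, b)$value, 1)      # all 4 final corners are in `a`
  expect_equal(hsc(b, a)$value, 0.5)    # only 4 of 8 final points matched
  expect_false(hsc(a, b)$value == hsc(b, a)$value)
})

test_that("one-to-one matching equals the brute-force oracle", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(8:40, 1)
    base <- ngon_slice(n, radius = stats::runif(1, 5, 20))
    noisy <- base
    keep <- stats::runif(n) < stats::runif(1)
    noisy$xy <- noisy$xy + (!keep) * matrix(stats::rnorm(2 * n, sd = 1), ncol = 2)
    fin <- contour_structure("f", list(base), slice_thickness = 3)
    ini <- contour_structure("i", list(noisy), slice_thickness = 3)
    for (tol in c(1e-6, 0.2, 0.8)) {
      expect_equal(hsc(ini, fin, match_tol = tol)$value,
                   oracle_hsc(ini, fin, tol))
    }
  }
  # a denser two-slice instance near the 200-point scale
  ph <- generate_phantom(phantom_spec(n_slices = 3, max_radius = 12,
                                      points_per_slice = 64, noise_amp = 1,
                                      seed = 2))
  warp <- ph
  warp$slices <- lapply(warp$slices, function(sl) {
    sl$xy <- sl$xy * 1.01
    sl
  })
  for (tol in c(0.05, 0.2, 0.5)) {
    expect_equal(hsc(warp, ph, match_tol = tol)$value, oracle_hsc(warp, ph, tol))
  }
})

test_that("one stationary initial point cannot certify many final points", {
  # all final points within tol of a single initial point
  fin <- one_slice_structure(ngon_slice(6, radius = 0.1), thickness = 3)
  ini <- one_slice_structure(
    slice_contour(cbind(c(0, 50, 50), c(0, 0, 50)), z = 0), thickness = 3)
  one <- hsc(ini, fin, match_tol = 0.5)
  expect_equal(one$n_untouched, 1L)
  many <- hsc(ini, fin, match_tol = 0.5, matching = "many_to_one")
  expect_equal(many$n_untouched, 6L)
})

test_that("DSC is symmetric with exact closed-form overlap", {
  ph <- small_phantom(seed = 6)
  g <- default_grid(ph)
  expect_equal(dsc(ph, ph, g)$value, 1)

  far <- translate_structure(ph, dx = 100)
  g2 <- default_grid(ph, far)
  expect_equal(dsc(ph, far, g2)$value, 0)

  a <- one_slice_structure(square_slice(2, x0 = 0, y0 = 0), thickness = 1)
  b <- one_slice_structure(slice_contour(
    cbind(c(1, 3, 3, 1), c(0, 0, 2, 2)), z = 0), thickness = 1)
  # margin chosen so no pixel center sits exactly on a square edge
  g3 <- default_grid(a, b, pixel_size = 0.05, margin = 0.977)
  expect_equal(dsc(a, b, g3)$value, 0.5, tolerance = 0.01)
  expect_equal(dsc(b, a, g3)$value, dsc(a, b, g3)$value)
})

test_that("DSC under concentric 3D scaling follows 2s^3/(1+s^3)", {
  sph <- generate_phantom(phantom_spec(n_slices = 25, slice_thickness = 3,
                                       max_radius = 40, points_per_slice = 64,
                                       superellipse_exponent = 2,
                                       noise_amp = 0, axial_profile = "sphere"))
  s <- 0.9
  shrunk <- scale_structure_3d(sph, s, center = c(0, 0, 0))
  g <- default_grid(sph, shrunk, pixel_size = 1, z_step = 1)
  expect_equal(dsc(sph, shrunk, g)$value, 2 * s^3 / (1 + s^3),
               tolerance = 0.01)
})

test_that("surface DSC matches concentric-circle geometry", {
  inner <- one_slice_structure(ngon_slice(256, 10), thickness = 3)
  outer <- one_slice_structure(ngon_slice(256, 12), thickness = 3)
  expect_equal(surface_dsc(inner, inner, tau = 0.1)$value, 1)
  expect_equal(surface_dsc(inner, outer, tau = 1)$value, 0)
  expect_equal(surface_dsc(inner, outer, tau = 3)$value, 1)
  expect_error(surface_dsc(inner, outer, tau = -1), ">= 0")
})

test_that("APL measures the unmatched final boundary length", {
  sq <- one_slice_structure(square_slice(2), thickness = 3)
  expect_equal(apl(sq, sq, tau = 0.01)$value, 0)

  far <- translate_structure(sq, dx = 50)
  expect_equal(apl(far, sq, tau = 1)$value, 8, tolerance = 1e-6)

  # initial covers the right edge and half of top and bottom: 4 mm shared
  half <- one_slice_structure(slice_contour(
    cbind(c(1, 2, 2, 1), c(0, 0, 2, 2)), z = 0), thickness = 3)
  expect_equal(apl(half, sq, tau = 0.01, sample_step = 0.005)$value, 4,
               tolerance = 0.1)
})

test_that("metric results carry provenance and serialize to rows", {
  ph <- small_phantom(seed = 13)
  off <- translate_structure(ph, dx = 0.2)
  panel <- metric_panel(off, ph, comparators = TRUE, tau = 1)
  expect_setequal(panel$metric,
                  c("HSC", "adapted_HSC", "DSC", "surface_DSC", "APL"))
  h <- panel[panel$metric == "HSC", ]
  expect_equal(h$n_total_final, n_boundary_points(ph))
  expect_error(metric_result(1, "HSC", n_untouched = 5L, n_total_final = 4L),
               "exceeds")
})
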