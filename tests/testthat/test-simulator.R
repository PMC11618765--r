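test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(phantom_spec(seed = 5))
  b <- generate_phantom(phantom_spec(seed = 5))
  expect_identical(structure_points(a), structure_points(b))
  c <- generate_phantom(phantom_spec(seed = 6))
  expect_gt(max(abs(structure_points(a) - structure_points(c))), 0.01)
  # generation must not disturb the caller's RNG stream
  set.seed(1); before <- stats::rnorm(1)
  set.seed(1); invisible(generate_phantom(phantom_spec(seed = 5)))
  expect_identical(stats::rnorm(1), before)
})

test_that("noise-free circular cylinder has analytic slice areas", {
  cyl <- generate_phantom(phantom_spec(n_slices = 6, max_radius = 25,
                                       points_per_slice = 64,
                                       superellipse_exponent = 2,
                                       noise_amp = 0,
                                       axial_profile = "cylinder"))
  areas <- vapply(cyl$slices, polygon_area, numeric(1))
  # a regular 64-gon underestimates the circle by sin(2*pi/64)*64/(2*pi)
  expect_equal(areas, rep(pi * 625, 6), tolerance = 0.005)
})

test_that("spherical phantom volume matches the analytic sphere", {
  sph <- generate_phantom(phantom_spec(n_slices = 27, slice_thickness = 3,
                                       max_radius = 40, points_per_slice = 64,
                                       superellipse_exponent = 2,
                                       noise_amp = 0, axial_profile = "sphere"))
  g <- default_grid(sph, pixel_size = 1)
  vol <- sum(rasterize_structure(sph, g)) * 1 * 1 * 3
  expect_equal(vol, 4 / 3 * pi * 40^3, tolerance = 0.02)
  expect_error(generate_phantom(phantom_spec(n_slices = 29, max_radius = 40,
                                             axial_profile = "sphere")),
               "does not fit")
})

test_that("shrink_slice is a centroid-anchored similarity transform", {
  sq <- square_slice(1)
  expect_identical(shrink_slice(sq, 1)$xy, sq$xy)

  half <- shrink_slice(sq, 0.5)
  expect_equal(polygon_centroid(half), polygon_centroid(sq))
  expect_equal(max(half$xy[, 1]) - min(half$xy[, 1]), 0.5)

  ph <- small_phantom(seed = 21)
  for (f in c(0.9, 0.6, 0.3)) {
    sl <- ph$slices[[3]]
    expect_equal(polygon_area(shrink_slice(sl, f)), f^2 * polygon_area(sl),
                 tolerance = 1e-9)
  }
  expect_error(shrink_slice(sq, 0), "\\(0, 1\\]")
  expect_error(shrink_slice(sq, 1.2), "\\(0, 1\\]")
})

test_that("hsc_from_untouched predicts the measured HSC exactly", {
  gt <- generate_phantom(phantom_spec())   # 28 slices x 64 points
  expect_equal(hsc_from_untouched(gt, integer(0)), 0)
  expect_equal(hsc_from_untouched(gt, 1:28), 1)
  expect_equal(hsc_from_untouched(gt, 1:13), 13 / 28)

  small <- small_phantom(seed = 2)
  untouched <- c(1, 2, 9, 10)
  built <- build_simulated_contour(small, untouched, factor = 0.8)
  expect_identical(hsc(built, small)$value,
                   hsc_from_untouched(small, untouched))
})

test_that("select_untouched_slices accumulates pole slices toward the target", {
  ph <- small_phantom(seed = 8)
  expect_identical(select_untouched_slices(ph, 0), integer(0))
  expect_identical(select_untouched_slices(ph, 1), 1:10)
  half <- select_untouched_slices(ph, 0.5)
  expect_equal(length(half), 5L)
  # pole slices (smallest areas) are picked before equatorial ones
  areas <- vapply(ph$slices, polygon_area, numeric(1))
  expect_true(max(areas[half]) <= min(areas[setdiff(1:10, half)]))
  expect_lte(abs(hsc_from_untouched(ph, half) - 0.5), 1 / 10 / 2)
})

test_that("DSC bisection matches the analytic cylinder oracle", {
  cyl <- generate_phantom(phantom_spec(n_slices = 8, max_radius = 20,
                                       points_per_slice = 64,
                                       superellipse_exponent = 2,
                                       noise_amp = 0,
                                       axial_profile = "cylinder"))
  g <- default_grid(cyl, pixel_size = 0.5)
  target <- 0.85
  sol <- solve_shrink_for_dsc(cyl, integer(0), target, g, tol = 0.002)
  f_analytic <- sqrt(target / (2 - target))  # root of 2f^2/(1+f^2) = target
  expect_equal(sol$factor, f_analytic, tolerance = 0.01)
  expect_equal(sol$achieved_dsc, target, tolerance = 0.002)
})

test_that("DSC is monotone increasing in the shrink factor", {
  ph <- small_phantom(seed = 17)
  g <- default_grid(ph)
  untouched <- c(1, 10)
  factors <- seq(0.3, 1, length.out = 10)
  vals <- vapply(factors, function(f) {
    dsc(build_simulated_contour(ph, untouched, f), ph, g)$value
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[10], 1)
})

test_that("infeasible DSC targets report the achievable floor", {
  ph <- small_phantom(seed = 3)
  g <- default_grid(ph)
  untouched <- select_untouched_slices(ph, 0.46)
  expect_error(solve_shrink_for_dsc(ph, untouched, 0.10, g), "floor")
  expect_error(solve_shrink_for_dsc(ph, 1:10, 0.9, g), "DSC = 1")
  tgt <- sim_target("fixed_dsc", 0.85, c(0, 1))
  expect_error(build_fixed_dsc_set(ph, tgt, g), "forces DSC = 1")
})

test_that("simulated contours stay inside the ground truth", {
  ph <- small_phantom(seed = 12)
  g <- default_grid(ph)
  tgt <- sim_target("fixed_dsc", 0.85, c(0.2, 0.5))
  set <- build_fixed_dsc_set(ph, tgt, g)
  gt_mask <- rasterize_structure(ph, g)
  for (cs in set) {
    m <- rasterize_structure(cs$structure, g)
    expect_true(all(gt_mask[m]))      # built mask is a subset of gt mask
    expect_lte(abs(cs$achieved_dsc - 0.85), 0.005)
  }
})

test_that("fixed-HSC construction shares one untouched set across cases", {
  ph <- small_phantom(seed = 30)
  g <- default_grid(ph)
  tgt <- sim_target("fixed_hsc", 0.5, c(0.75, 0.85, 0.95))
  set <- build_fixed_hsc_set(ph, tgt, g)
  hscs <- vapply(set, function(cs) cs$achieved_hsc, numeric(1))
  expect_equal(length(unique(hscs)), 1L)
  dscs <- vapply(set, function(cs) cs$achieved_dsc, numeric(1))
  expect_equal(dscs, c(0.75, 0.85, 0.95), tolerance = 0.005)
  man <- sim_manifest(set)
  expect_equal(nrow(man), 3L)
  expect_equal(length(unique(man$untouched)), 1L)
})
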