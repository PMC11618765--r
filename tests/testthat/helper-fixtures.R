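# Shared in-code fixtures and independent oracles.

# axis-aligned square as a slice contour (CCW from the lower-left corner)
square_slice <- function(side = 1, z = 0, x0 = 0, y0 = 0) {
  slice_contour(cbind(c(x0, x0 + side, x0 + side, x0),
                      c(y0, y0, y0 + side, y0 + side)), z = z)
}

# single-slice structure wrapping one contour
one_slice_structure <- function(sl, name = "fix", thickness = 1) {
  contour_structure(name, list(sl), slice_thickness = thickness)
}

# regular n-gon of given radius as a slice contour
ngon_slice <- function(n, radius, z = 0, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  slice_contour(cbind(cx + radius * cos(th), cy + radius * sin(th)), z = z,
                check_simple = FALSE)
}

# small noisy phantom kept cheap enough for per-test regeneration
small_phantom <- function(seed = 7, n_slices = 10, points = 32) {
  generate_phantom(phantom_spec(n_slices = n_slices, max_radius = 15,
                                points_per_slice = points, noise_amp = 0.5,
                                seed = seed))
}

# Independent O(n^2) brute-force HSC oracle: same matching discipline
# (per paired slice, one-to-one greedy by ascending 3D distance) written
# as plain loops without the package's matrix machinery.
oracle_hsc <- function(initial, final, tol) {
  zi <- vapply(initial$slices, function(s) s$z, numeric(1))
  n_t <- 0L
  n_u <- 0L
  for (fs in final$slices) {
    n_f <- nrow(fs$xy)
    n_t <- n_t + n_f
    dz <- abs(zi - fs$z)
    k <- which.min(dz)
    if (dz[k] > final$slice_thickness / 2 + 1e-9) next
    is_xy <- initial$slices[[k]]$xy
    zoff <- zi[k] - fs$z
    pairs <- NULL
    for (i in seq_len(n_f)) {
      for (j in seq_len(nrow(is_xy))) {
        d <- sqrt(sum((fs$xy[i, ] - is_xy[j, ])^2) + zoff^2)
        if (d <= tol) pairs <- rbind(pairs, c(i, j, d))
      }
    }
    if (is.null(pairs)) next
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    used_f <- logical(n_f); used_i <- logical(nrow(is_xy))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!used_f[i] && !used_i[j]) {
        used_f[i] <- TRUE; used_i[j] <- TRUE
        n_u <- n_u + 1L
      }
    }
  }
  n_u / n_t
}

# brute-force pixel count of a polygon mask via an independent
# point-in-polygon routine (pracma) over all pixel centers
oracle_pixel_count <- function(sl, g) {
  px <- g$origin[1] + (seq_len(g$shape[2]) - 1) * g$pixel_size
  py <- g$origin[2] + (seq_len(g$shape[1]) - 1) * g$pixel_size
  xg <- rep(px, each = g$shape[1])
  yg <- rep(py, times = g$shape[2])
  sum(pracma::inpolygon(xg, yg, sl$xy[, 1], sl$xy[, 2], boundary = TRUE))
}
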