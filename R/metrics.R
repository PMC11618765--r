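#' @title Metric result container
#' @description Constructor for the value-plus-provenance record returned
#'   by every metric in the package: the metric value together with the
#'   boundary-point counts, tolerances and grid that produced it, so a
#'   reported number can always be traced to its inputs.
#' @param value metric value.
#' @param metric_name label ("HSC", "adapted_HSC", "DSC", ...).
#' @param n_untouched untouched boundary-point count N_U (HSC family).
#' @param n_total_final total final-contour boundary-point count N_T.
#' @param match_tol point-matching tolerance in mm, if any.
#' @param grid the `raster_grid` used, if any.
#' @param extra named list of additional provenance fields.
#' @return an object of class `metric_result`.
#' @export
metric_result <- function(value, metric_name, n_untouched = NA_integer_,
                          n_total_final = NA_integer_, match_tol = NA_real_,
                          grid = NULL, extra = list()) {
  if (!is.na(n_untouched) && !is.na(n_total_final) &&
      n_untouched > n_total_final) {
    stop("metric_result(): n_untouched exceeds n_total_final", call. = FALSE)
  }
  out <- c(list(value = as.numeric(value), metric_name = metric_name,
                n_untouched = n_untouched, n_total_final = n_total_final,
                match_tol = match_tol, grid = grid), extra)
  class(out) <- "metric_result"
  out
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$metric_name, x$value))
  if (!is.na(x$n_untouched)) {
    cat(sprintf("  (N_U = %d, N_T = %d, match_tol = %g mm)",
                x$n_untouched, x$n_total_final, x$match_tol))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.metric_result <- function(x, ...) {
  data.frame(metric = x$metric_name, value = x$value,
             n_untouched = x$n_untouched, n_total_final = x$n_total_final,
             match_tol = x$match_tol, stringsAsFactors = FALSE)
}

# pair each final slice with the nearest initial slice within half the
# final structure's slice thickness; contour editing is per slice, so
# cross-slice point matches are never allowed
pair_slices <- function(initial, final) {
  zi <- slice_z(initial)
  tol <- final$slice_thickness / 2
  vapply(slice_z(final), function(zf) {
    d <- abs(zi - zf)
    k <- which.min(d)
    if (d[k] <= tol + 1e-9) k else NA_integer_
  }, integer(1L))
}

# one-to-one matching of final points to initial points within `tol`,
# greedy by ascending distance; returns the number of final points matched
match_points_one_to_one <- function(fin_xy, ini_xy, tol) {
  d2 <- outer(rowSums(fin_xy^2), rowSums(ini_xy^2), "+") -
    2 * tcrossprod(fin_xy, ini_xy)
  d2[d2 < 0] <- 0
  cand <- which(d2 <= tol^2 + 1e-300, arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  ord <- order(d2[cand])
  cand <- cand[ord, , drop = FALSE]
  used_f <- logical(nrow(fin_xy))
  used_i <- logical(nrow(ini_xy))
  n <- 0L
  for (k in seq_len(nrow(cand))) {
    f <- cand[k, 1L]; i <- cand[k, 2L]
    if (!used_f[f] && !used_i[i]) {
      used_f[f] <- TRUE
      used_i[i] <- TRUE
      n <- n + 1L
    }
  }
  n
}

match_points_many_to_one <- function(fin_xy, ini_xy, tol) {
  d2 <- outer(rowSums(fin_xy^2), rowSums(ini_xy^2), "+") -
    2 * tcrossprod(fin_xy, ini_xy)
  sum(apply(d2, 1L, min) <= tol^2 + 1e-300)
}

#' Hu similarity coefficient
#'
#' HSC = N_U / N_T: the fraction of final-contour boundary points left
#' untouched when an initial (for example auto-generated) contour is
#' adjusted into the final, clinically acceptable one. N_T is the total
#' boundary-point count of the final contour; N_U counts final points for
#' which an initial point lies within `match_tol` (3D Euclidean distance,
#' restricted to paired slices). The metric is asymmetric by design: the
#' denominator is always the final contour, so an initial contour with
#' extra points can never push the value above 1.
#'
#' A value of 1 means the initial contour can be used as-is; 0 means the
#' entire contour had to be redrawn, equivalent to contouring from
#' scratch.
#'
#' @param initial the contour before adjustment.
#' @param final the contour after adjustment (denominator of the ratio).
#' @param match_tol matching tolerance in mm. The default 1e-6 mm
#'   operationalizes "coordinates unchanged" while tolerating float noise
#'   from I/O round-trips.
#' @param matching `"one_to_one"` (default; each initial point may certify
#'   at most one final point, matched greedily by ascending distance) or
#'   `"many_to_one"`.
#' @return a [metric_result] with `value`, `n_untouched` (N_U) and
#'   `n_total_final` (N_T).
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 5, max_radius = 10,
#'                                     points_per_slice = 16))
#' hsc(ph, ph)$value  # 1: nothing was touched
#' @export
hsc <- function(initial, final, match_tol = 1e-6,
                matching = c("one_to_one", "many_to_one")) {
  stopifnot(inherits(initial, "contour_structure"),
            inherits(final, "contour_structure"))
  matching <- match.arg(matching)
  if (!is.numeric(match_tol) || match_tol < 0) {
    stop("hsc(): 'match_tol' must be >= 0", call. = FALSE)
  }
  if (!length(final$slices)) {
    stop("hsc(): empty final structure", call. = FALSE)
  }
  pairing <- pair_slices(initial, final)
  n_t <- n_boundary_points(final)
  n_u <- 0L
  for (k in seq_along(final$slices)) {
    if (is.na(pairing[k])) next
    fin_sl <- final$slices[[k]]
    ini_sl <- initial$slices[[pairing[k]]]
    dz <- fin_sl$z - ini_sl$z
    fin_xyz <- cbind(fin_sl$xy, 0)
    ini_xyz <- cbind(ini_sl$xy, dz)  # relative z offset enters the distance
    n_u <- n_u + switch(matching,
      one_to_one = match_points_one_to_one(fin_xyz, ini_xyz, match_tol),
      many_to_one = match_points_many_to_one(fin_xyz, ini_xyz, match_tol))
  }
  metric_result(n_u / n_t, "HSC", n_untouched = n_u, n_total_final = n_t,
                match_tol = match_tol, extra = list(matching = matching))
}

#' Tolerance-adapted Hu similarity coefficient
#'
#' Same ratio as [hsc()], but a final boundary point whose nearest initial
#' point deviates by less than a clinically indistinguishable distance
#' (default 0.5 mm) is treated as requiring no modification. This rescues
#' the degenerate case where two clinically identical contours are offset
#' by a sub-resolution amount, which drives the exact-tolerance HSC to 0.
#'
#' @inheritParams hsc
#' @param clinical_tol geometric-deviation tolerance in mm (> 0,
#'   default 0.5).
#' @return a [metric_result].
#' @export
adapted_hsc <- function(initial, final, clinical_tol = 0.5,
                        matching = c("one_to_one", "many_to_one")) {
  if (!is.numeric(clinical_tol) || clinical_tol <= 0) {
    stop("adapted_hsc(): 'clinical_tol' must be > 0", call. = FALSE)
  }
  out <- hsc(initial, final, match_tol = clinical_tol, matching = matching)
  out$metric_name <- "adapted_HSC"
  out
}

#' Volumetric Dice similarity coefficient
#'
#' DSC = 2|A intersect B| / (|A| + |B|) over the voxels of the two
#' rasterized structures: symmetric, 1 for identical masks, 0 for
#' disjoint ones.
#'
#' @param a,b `contour_structure` objects.
#' @param g a `raster_grid`; defaults to a 1 mm grid covering both.
#' @return a [metric_result] carrying the grid used and voxel counts.
#' @export
dsc <- function(a, b, g = NULL) {
  stopifnot(inherits(a, "contour_structure"), inherits(b, "contour_structure"))
  if (is.null(g)) g <- default_grid(a, b)
  ma <- rasterize_structure(a, g)
  mb <- rasterize_structure(b, g)
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) {
    stop("dsc(): both masks are empty on this grid; DSC undefined",
         call. = FALSE)
  }
  inter <- sum(ma & mb)
  metric_result(2 * inter / (na + nb), "DSC", grid = g,
                extra = list(voxels_a = na, voxels_b = nb,
                             voxels_intersection = inter))
}

# equally spaced samples (with segment weights) along a closed ring
boundary_samples <- function(sl, step) {
  per <- polygon_perimeter(sl)
  n <- max(8L, ceiling(per / step))
  res <- resample_contour(sl, n)
  list(xy = res$xy, w = rep(per / n, n), perimeter = per)
}

# distance from each point to the nearest segment of a closed ring
min_dist_to_ring <- function(pts, ring) {
  n <- nrow(ring)
  j <- c(2:n, 1L)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[j[i], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) {
      pmin(1, pmax(0, ((pts[, 1L] - a[1L]) * ab[1L] +
                         (pts[, 2L] - a[2L]) * ab[2L]) / len2))
    } else 0
    dx <- pts[, 1L] - (a[1L] + t * ab[1L])
    dy <- pts[, 2L] - (a[2L] + t * ab[2L])
    best <- pmin(best, sqrt(dx * dx + dy * dy))
  }
  best
}

#' Surface Dice coefficient (slice-wise comparator, simplified)
#'
#' Fraction of boundary length lying within a distance `tau` of the other
#' contour's boundary, averaged over both directions with perimeter
#' weights — a 2D slice-wise boundary version of the surface Dice,
#' provided as a simplified comparator. Slices of one structure with no
#' paired slice in the other contribute fully unmatched boundary.
#'
#' @param a,b `contour_structure` objects.
#' @param tau distance tolerance in mm (>= 0).
#' @param sample_step boundary sampling step in mm.
#' @return a [metric_result].
#' @export
surface_dsc <- function(a, b, tau, sample_step = 0.2) {
  stopifnot(inherits(a, "contour_structure"), inherits(b, "contour_structure"))
  if (!is.numeric(tau) || tau < 0) stop("surface_dsc(): 'tau' must be >= 0",
                                        call. = FALSE)
  if (!length(a$slices) || !length(b$slices)) {
    stop("surface_dsc(): empty structure", call. = FALSE)
  }
  direction <- function(from, to) {
    pairing <- pair_slices(to, from)  # for each slice of `from`, slice of `to`
    tot <- 0; near <- 0
    for (k in seq_along(from$slices)) {
      s <- boundary_samples(from$slices[[k]], sample_step)
      tot <- tot + s$perimeter
      if (is.na(pairing[k])) next
      dmin <- min_dist_to_ring(s$xy, to$slices[[pairing[k]]]$xy)
      near <- near + sum(s$w[dmin <= tau + 1e-12])
    }
    c(near = near, tot = tot)
  }
  ab <- direction(a, b)
  ba <- direction(b, a)
  metric_result((ab["near"] + ba["near"]) / (ab["tot"] + ba["tot"]),
                "surface_DSC", match_tol = tau,
                extra = list(sample_step = sample_step))
}

#' Added path length
#'
#' Total arc length of the final contour's boundary lying farther than
#' `tau` from the initial contour's boundary: the length of boundary that
#' had to be drawn or redrawn to reach the final contour. Slice-wise 2D
#' boundary comparator (simplified); final slices with no paired initial
#' slice count in full.
#'
#' @param initial,final `contour_structure` objects.
#' @param tau distance tolerance in mm (default 1.0, the in-plane pixel
#'   size the defaults emulate).
#' @param sample_step boundary sampling step in mm.
#' @return added path length in mm (a [metric_result] with `value` in mm).
#' @export
apl <- function(initial, final, tau = 1.0, sample_step = 0.2) {
  stopifnot(inherits(initial, "contour_structure"),
            inherits(final, "contour_structure"))
  if (!is.numeric(tau) || tau < 0) stop("apl(): 'tau' must be >= 0",
                                        call. = FALSE)
  if (!length(final$slices)) stop("apl(): empty final structure", call. = FALSE)
  pairing <- pair_slices(initial, final)
  added <- 0
  for (k in seq_along(final$slices)) {
    s <- boundary_samples(final$slices[[k]], sample_step)
    if (is.na(pairing[k])) {
      added <- added + s$perimeter
      next
    }
    dmin <- min_dist_to_ring(s$xy, initial$slices[[pairing[k]]]$xy)
    added <- added + sum(s$w[dmin > tau + 1e-12])
  }
  metric_result(added, "APL", match_tol = tau,
                extra = list(sample_step = sample_step, units = "mm"))
}

#' Compute the standard metric panel for a contour pair
#'
#' @param initial,final `contour_structure` objects.
#' @param match_tol exact-HSC matching tolerance, mm.
#' @param clinical_tol adapted-HSC tolerance, mm.
#' @param pixel_size DSC raster pixel size, mm.
#' @param comparators also compute surface DSC and APL (at `tau`).
#' @param tau surface-DSC/APL distance tolerance, mm.
#' @return data.frame of metric rows (one per metric) with provenance.
#' @export
metric_panel <- function(initial, final, match_tol = 1e-6, clinical_tol = 0.5,
                         pixel_size = 1, comparators = FALSE, tau = 1.0) {
  g <- default_grid(initial, final, pixel_size = pixel_size)
  res <- list(
    hsc(initial, final, match_tol = match_tol),
    adapted_hsc(initial, final, clinical_tol = clinical_tol),
    dsc(initial, final, g)
  )
  if (comparators) {
    res <- c(res, list(surface_dsc(initial, final, tau = tau),
                       apl(initial, final, tau = tau)))
  }
  do.call(rbind, lapply(res, as.data.frame))
}
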