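#' Construct a single closed planar contour
#'
#' A slice contour is one closed, simple (non-self-intersecting) polygon
#' lying in a plane of constant z, stored as an ordered ring of boundary
#' points in patient coordinates (mm). The ring is stored open: the first
#' vertex is not repeated at the end, closure is implicit. On construction
#' the vertex order is normalized to counter-clockwise; the original
#' orientation is kept as an attribute so files can be round-tripped.
#'
#' @param points numeric matrix with 2 columns (x, y) or 3 columns
#'   (x, y, z), one row per boundary point, in mm. At least 3 points.
#' @param z slice plane coordinate in mm. Required for 2-column input;
#'   for 3-column input it defaults to the common z of the points, which
#'   must agree within 1e-9 mm.
#' @param check_simple check that the polygon does not self-intersect
#'   (O(n^2); disable for large trusted rings).
#' @return an object of class `slice_contour`: a list with elements
#'   `z` (mm) and `xy` (n x 2 matrix of vertex coordinates, CCW).
#' @examples
#' sq <- slice_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), z = 0)
#' polygon_area(sq)
#' @export
slice_contour <- function(points, z = NULL, check_simple = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) == 3L) {
    zs <- points[, 3L]
    if (is.null(z)) z <- zs[1L]
    if (any(abs(zs - z) > 1e-9)) {
      stop("slice_contour(): points are not coplanar at z = ", z,
           " (max deviation ", max(abs(zs - z)), " mm)", call. = FALSE)
    }
    points <- points[, 1:2, drop = FALSE]
  } else if (ncol(points) != 2L) {
    stop("slice_contour(): 'points' must have 2 or 3 columns", call. = FALSE)
  }
  if (is.null(z)) stop("slice_contour(): 'z' is required for 2-column input",
                       call. = FALSE)
  if (!all(is.finite(points)) || !is.finite(z)) {
    stop("slice_contour(): all coordinates must be finite", call. = FALSE)
  }
  # drop a duplicated closing vertex if the caller supplied one
  n <- nrow(points)
  if (n >= 4L && all(abs(points[1L, ] - points[n, ]) < 1e-12)) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop("slice_contour(): need at least 3 distinct points",
                   call. = FALSE)
  a <- signed_area(points)
  if (abs(a) < 1e-12) {
    stop("slice_contour(): degenerate polygon (zero area)", call. = FALSE)
  }
  orientation <- if (a > 0) "ccw" else "cw"
  if (a < 0) points <- points[rev(seq_len(n)), , drop = FALSE]
  if (check_simple && !ring_is_simple(points)) {
    stop("slice_contour(): polygon is self-intersecting", call. = FALSE)
  }
  out <- list(z = as.numeric(z), xy = unname(points))
  attr(out, "orientation") <- orientation
  class(out) <- "slice_contour"
  out
}

# shoelace signed area of an open ring (CCW positive)
signed_area <- function(xy) {
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  sum(xy[j, 1L] * xy[, 2L] - xy[, 1L] * xy[j, 2L]) / 2
}

# segment-intersection scan; O(n^2) but rings are small (tens of points)
ring_is_simple <- function(xy) {
  n <- nrow(xy)
  p1 <- xy
  p2 <- xy[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # skip edges sharing a vertex with edge 1
    if (!length(js)) next
    if (any(segments_intersect(p1[i, ], p2[i, ], p1[js, , drop = FALSE],
                               p2[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(a1, a2, b1, b2) {
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross2(b1[, 1L], b1[, 2L], b2[, 1L], b2[, 2L], a1[1L], a1[2L])
  d2 <- cross2(b1[, 1L], b1[, 2L], b2[, 1L], b2[, 2L], a2[1L], a2[2L])
  d3 <- cross2(a1[1L], a1[2L], a2[1L], a2[2L], b1[, 1L], b1[, 2L])
  d4 <- cross2(a1[1L], a1[2L], a2[1L], a2[2L], b2[, 1L], b2[, 2L])
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Construct an organ structure from a stack of slice contours
#'
#' A structure is a named organ represented as slice contours ordered by
#' strictly increasing z, one contour per slice (multi-ring slices are out
#' of scope). Mirrors how a DICOM RT Structure Set stores an ROI.
#'
#' @param name structure (ROI) label.
#' @param slices list of [slice_contour] objects; sorted by z on ingest.
#' @param slice_thickness axial spacing in mm (default 3, a common CT
#'   slice thickness for pelvic imaging).
#' @return an object of class `contour_structure`.
#' @export
contour_structure <- function(name, slices, slice_thickness = 3) {
  if (!length(slices)) {
    stop("contour_structure(): at least one slice is required", call. = FALSE)
  }
  ok <- vapply(slices, inherits, logical(1L), what = "slice_contour")
  if (!all(ok)) stop("contour_structure(): 'slices' must be slice_contour objects",
                     call. = FALSE)
  zs <- vapply(slices, function(s) s$z, numeric(1L))
  o <- order(zs)
  slices <- slices[o]
  zs <- zs[o]
  if (any(diff(zs) <= 1e-9)) {
    stop("contour_structure(): slice z values must be strictly increasing; ",
         "duplicate z = ", zs[which(diff(zs) <= 1e-9)[1L] + 1L], call. = FALSE)
  }
  if (!is.numeric(slice_thickness) || slice_thickness <= 0) {
    stop("contour_structure(): 'slice_thickness' must be > 0", call. = FALSE)
  }
  out <- list(name = as.character(name), slices = slices,
              slice_thickness = as.numeric(slice_thickness))
  class(out) <- "contour_structure"
  out
}

#' @export
print.contour_structure <- function(x, ...) {
  cat(sprintf("<contour_structure> '%s': %d slices, %d boundary points, dz = %g mm\n",
              x$name, length(x$slices), n_boundary_points(x), x$slice_thickness))
  zr <- range(slice_z(x))
  cat(sprintf("  z range [%g, %g] mm\n", zr[1L], zr[2L]))
  invisible(x)
}

#' Slice z coordinates of a structure
#' @param s a `contour_structure`.
#' @return numeric vector of slice plane z values (mm), increasing.
#' @export
slice_z <- function(s) vapply(s$slices, function(x) x$z, numeric(1L))

#' Total boundary-point count of a structure
#'
#' The denominator N_T of the HSC when `s` is the final contour.
#' @param s a `contour_structure`.
#' @return integer count of boundary points over all slices.
#' @export
n_boundary_points <- function(s) {
  sum(vapply(s$slices, function(x) nrow(x$xy), integer(1L)))
}

#' All boundary points of a structure as an (x, y, z) matrix
#' @param s a `contour_structure`.
#' @return numeric matrix with columns x, y, z (mm), slices in z order.
#' @export
structure_points <- function(s) {
  do.call(rbind, lapply(s$slices, function(sl) {
    cbind(sl$xy, rep(sl$z, nrow(sl$xy)))
  }))
}

#' Polygon area of a slice contour
#'
#' Absolute shoelace area of the closed ring, in mm^2.
#' @param c a `slice_contour`.
#' @return area in mm^2 (> 0).
#' @export
polygon_area <- function(c) {
  stopifnot(inherits(c, "slice_contour"))
  abs(signed_area(c$xy))
}

#' Area-weighted centroid of a slice contour
#' @param c a `slice_contour`.
#' @return numeric (x, y, z) of the polygon centroid, z being the slice plane.
#' @export
polygon_centroid <- function(c) {
  stopifnot(inherits(c, "slice_contour"))
  xy <- c$xy
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cr <- xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("polygon_centroid(): degenerate polygon", call. = FALSE)
  cx <- sum((xy[, 1L] + xy[j, 1L]) * cr) / (6 * a)
  cy <- sum((xy[, 2L] + xy[j, 2L]) * cr) / (6 * a)
  c(x = cx, y = cy, z = c$z)
}

#' Perimeter of a slice contour
#' @param c a `slice_contour`.
#' @return boundary length in mm.
#' @export
polygon_perimeter <- function(c) {
  stopifnot(inherits(c, "slice_contour"))
  xy <- c$xy
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(sqrt(rowSums((xy[j, , drop = FALSE] - xy)^2)))
}

#' Resample a slice contour to a fixed number of boundary points
#'
#' Places `n` points at equal arc-length spacing along the original closed
#' boundary; the first output point coincides with the original first
#' vertex. Used to fix the boundary point count before radial scaling in
#' the simulator.
#'
#' @param c a `slice_contour`.
#' @param n number of output points (>= 3).
#' @return a `slice_contour` with `n` points.
#' @export
resample_contour <- function(c, n) {
  stopifnot(inherits(c, "slice_contour"))
  n <- as.integer(n)
  if (is.na(n) || n < 3L) {
    stop("resample_contour(): 'n' must be >= 3", call. = FALSE)
  }
  xy <- c$xy
  m <- nrow(xy)
  nxt <- c(2:m, 1L)
  seg <- sqrt(rowSums((xy[nxt, , drop = FALSE] - xy)^2))
  cum <- c(0, cumsum(seg))      # length m + 1; cum[m+1] = perimeter
  per <- cum[m + 1L]
  targets <- per * (seq_len(n) - 1L) / n
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (targets - cum[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  new_xy <- xy[idx, , drop = FALSE] +
    (xy[nxt[idx], , drop = FALSE] - xy[idx, , drop = FALSE]) * frac
  slice_contour(new_xy, z = c$z, check_simple = FALSE)
}

#' Translate a structure rigidly
#' @param s a `contour_structure`.
#' @param dx,dy,dz offsets in mm.
#' @return the translated `contour_structure`.
#' @export
translate_structure <- function(s, dx = 0, dy = 0, dz = 0) {
  s$slices <- lapply(s$slices, function(sl) {
    sl$xy[, 1L] <- sl$xy[, 1L] + dx
    sl$xy[, 2L] <- sl$xy[, 2L] + dy
    sl$z <- sl$z + dz
    sl
  })
  s
}

#' Scale a structure uniformly in 3D about a fixed point
#'
#' Scales x, y and z by the same factor about `center`; slice thickness is
#' scaled too. Used for concentric-scaling checks of volumetric overlap.
#' @param s a `contour_structure`.
#' @param factor scale factor (> 0).
#' @param center length-3 numeric (x, y, z) fixed point; default the mean
#'   of the slice-z range and the mean slice centroid.
#' @return the scaled `contour_structure`.
#' @export
scale_structure_3d <- function(s, factor, center = NULL) {
  stopifnot(is.numeric(factor), factor > 0)
  if (is.null(center)) {
    cen <- vapply(s$slices, polygon_centroid, numeric(3L))
    center <- c(mean(cen[1L, ]), mean(cen[2L, ]), mean(range(slice_z(s))))
  }
  s$slices <- lapply(s$slices, function(sl) {
    sl$xy[, 1L] <- center[1L] + factor * (sl$xy[, 1L] - center[1L])
    sl$xy[, 2L] <- center[2L] + factor * (sl$xy[, 2L] - center[2L])
    sl$z <- center[3L] + factor * (sl$z - center[3L])
    sl
  })
  s$slice_thickness <- s$slice_thickness * factor
  s
}
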