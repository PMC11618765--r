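#' Define a raster grid for mask-based metrics
#'
#' The grid on which structures are rasterized for volumetric overlap.
#' In-plane sampling is isotropic; `origin` is the center of the first
#' pixel (row 1, col 1). Columns advance along x, rows along y.
#'
#' @param origin length-2 numeric, (x, y) of the first pixel center, mm.
#' @param pixel_size in-plane pixel size in mm (default 1.0, the in-plane
#'   CT pixel size the metric defaults emulate).
#' @param shape integer (rows, cols).
#' @param z_planes strictly increasing z coordinates of the grid planes, mm.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(origin, pixel_size = 1, shape, z_planes) {
  stopifnot(length(origin) == 2L, is.numeric(pixel_size), pixel_size > 0,
            length(shape) == 2L, all(shape >= 1), length(z_planes) >= 1L)
  z_planes <- as.numeric(z_planes)
  if (length(z_planes) > 1L && any(diff(z_planes) <= 0)) {
    stop("raster_grid(): 'z_planes' must be strictly increasing", call. = FALSE)
  }
  out <- list(origin = as.numeric(origin), pixel_size = as.numeric(pixel_size),
              shape = as.integer(shape), z_planes = z_planes)
  class(out) <- "raster_grid"
  out
}

#' Build a grid that covers one or two structures
#'
#' Convenience constructor: the in-plane extent is the joint bounding box
#' plus a margin, and the z planes default to the union of the structures'
#' slice planes (so each slice maps to exactly one plane). A finer axial
#' sampling can be requested with `z_step` for sub-slice volume estimates.
#'
#' @param a a `contour_structure`.
#' @param b optional second structure to cover.
#' @param pixel_size in-plane pixel size, mm.
#' @param margin extra in-plane margin, mm.
#' @param z_step optional axial sampling step in mm; when given, planes are
#'   laid out at this spacing across the joint z extent (padded by half a
#'   slice thickness each side).
#' @return a `raster_grid`.
#' @export
default_grid <- function(a, b = NULL, pixel_size = 1, margin = 5, z_step = NULL) {
  pts <- structure_points(a)
  if (!is.null(b)) pts <- rbind(pts, structure_points(b))
  xr <- range(pts[, 1L]) + c(-margin, margin)
  yr <- range(pts[, 2L]) + c(-margin, margin)
  shape <- c(ceiling(diff(yr) / pixel_size) + 1L,
             ceiling(diff(xr) / pixel_size) + 1L)
  if (is.null(z_step)) {
    zs <- slice_z(a)
    if (!is.null(b)) zs <- c(zs, slice_z(b))
    zs <- sort(unique(round(zs, 9)))
    keep <- c(TRUE, diff(zs) > 1e-6)
    zs <- zs[keep]
  } else {
    th <- max(a$slice_thickness, if (!is.null(b)) b$slice_thickness else 0)
    zr <- range(c(slice_z(a), if (!is.null(b)) slice_z(b))) +
      c(-th / 2, th / 2)
    zs <- seq(zr[1L], zr[2L], by = z_step)
  }
  raster_grid(origin = c(xr[1L], yr[1L]), pixel_size = pixel_size,
              shape = shape, z_planes = zs)
}

# vectorized even-odd point-in-polygon; points exactly on an edge count as
# inside (deterministic mask convention, documented in the vignette)
point_in_polygon <- function(px, py, xy, edge_eps = 1e-9) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (i in seq_len(n)) {
    x1 <- xy[i, 1L]; y1 <- xy[i, 2L]
    x2 <- xy[j[i], 1L]; y2 <- xy[j[i], 2L]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- crosses
      hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
    # on-segment test: zero cross product and within the bounding box
    d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    near <- d <= edge_eps * max(1, seg_len) &
      px >= pmin(x1, x2) - edge_eps & px <= pmax(x1, x2) + edge_eps &
      py >= pmin(y1, y2) - edge_eps & py <= pmax(y1, y2) + edge_eps
    on_edge <- on_edge | near
  }
  inside | on_edge
}

# mask of one slice contour on the in-plane grid (logical rows x cols)
rasterize_slice <- function(sl, g) {
  px <- g$origin[1L] + (seq_len(g$shape[2L]) - 1L) * g$pixel_size
  py <- g$origin[2L] + (seq_len(g$shape[1L]) - 1L) * g$pixel_size
  xg <- rep(px, each = g$shape[1L])
  yg <- rep(py, times = g$shape[2L])
  matrix(point_in_polygon(xg, yg, sl$xy), nrow = g$shape[1L])
}

#' Rasterize a structure to a binary volume
#'
#' Per-plane even-odd polygon fill: a pixel belongs to the mask when its
#' center lies inside (or exactly on the boundary of) the slice polygon.
#' Each grid plane takes the contour of the structure slice whose z lies
#' within half the structure's slice thickness (nearest when several
#' qualify); planes with no matching slice are all zero. Every structure
#' slice must map to at least one grid plane.
#'
#' @param s a `contour_structure`.
#' @param g a `raster_grid`.
#' @return logical array (rows, cols, planes).
#' @export
rasterize_structure <- function(s, g) {
  zs <- slice_z(s)
  tol <- s$slice_thickness / 2
  # plane -> slice assignment
  assign_idx <- vapply(g$z_planes, function(zp) {
    d <- abs(zs - zp)
    k <- which.min(d)
    if (d[k] <= tol + 1e-9) k else NA_integer_
  }, integer(1L))
  if (!all(seq_along(zs) %in% assign_idx)) {
    miss <- setdiff(seq_along(zs), assign_idx)
    stop("rasterize_structure(): slice at z = ", zs[miss[1L]],
         " mm matches no grid plane", call. = FALSE)
  }
  vol <- array(FALSE, dim = c(g$shape[1L], g$shape[2L], length(g$z_planes)))
  cache <- vector("list", length(zs))
  for (p in seq_along(g$z_planes)) {
    k <- assign_idx[p]
    if (is.na(k)) next
    if (is.null(cache[[k]])) cache[[k]] <- rasterize_slice(s$slices[[k]], g)
    vol[, , p] <- cache[[k]]
  }
  vol
}

#' Read a structure from the plain JSON contour dialect
#'
#' Schema (versioned copy in `inst/extdata/contour-json-schema.json`):
#' `{"format": "contour-json/1", "name": ..., "slice_thickness": ...,
#'   "slices": [{"z": ..., "points": [[x, y, z], ...]}, ...]}`.
#' Slices stored out of z order are accepted, sorted on ingest, and a
#' warning is raised.
#'
#' @param path file path.
#' @return a `contour_structure`.
#' @export
read_json_contours <- function(path) {
  if (!file.exists(path)) {
    stop("read_json_contours(): no such file: ", path, call. = FALSE)
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("read_json_contours(): not valid JSON (", path, "): ",
                         conditionMessage(e), call. = FALSE)
                  })
  req <- c("name", "slice_thickness", "slices")
  if (!is.list(obj) || !all(req %in% names(obj))) {
    stop("read_json_contours(): schema violation, required fields: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  sl_raw <- obj$slices
  # simplifyVector may give a data.frame of z + list of point matrices
  if (is.data.frame(sl_raw)) {
    zs <- sl_raw$z
    pts <- sl_raw$points
  } else {
    zs <- vapply(sl_raw, function(x) as.numeric(x$z), numeric(1L))
    pts <- lapply(sl_raw, function(x) x$points)
  }
  if (!length(zs)) stop("read_json_contours(): schema violation: empty 'slices'",
                        call. = FALSE)
  if (is.unsorted(zs, strictly = TRUE)) {
    warning("read_json_contours(): slices not sorted by z in ", path,
            "; sorting on ingest")
  }
  slices <- lapply(seq_along(zs), function(i) {
    m <- pts[[i]]
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    m <- as.matrix(m)
    if (ncol(m) != 3L) {
      stop("read_json_contours(): schema violation: points must be ",
           "[x, y, z] triplets", call. = FALSE)
    }
    slice_contour(m, z = zs[i])
  })
  contour_structure(obj$name, slices, slice_thickness = obj$slice_thickness)
}

#' Write a structure to the plain JSON contour dialect
#'
#' @param s a `contour_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_json_contours <- function(s, path) {
  stopifnot(inherits(s, "contour_structure"))
  slices <- lapply(s$slices, function(sl) {
    ring <- restore_orientation(sl)
    list(z = sl$z,
         points = cbind(ring, rep(sl$z, nrow(ring))))
  })
  obj <- list(format = "contour-json/1",
              name = s$name,
              slice_thickness = s$slice_thickness,
              slices = slices)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# undo the CCW normalization for round-trip fidelity of point order
restore_orientation <- function(sl) {
  if (identical(attr(sl, "orientation"), "cw")) {
    sl$xy[rev(seq_len(nrow(sl$xy))), , drop = FALSE]
  } else {
    sl$xy
  }
}

#' Read a structure file, dispatching on its format
#'
#' Recognizes the JSON contour dialect (`.json`) and DICOM RT Structure
#' Set files (anything else, sniffed for the DICM magic).
#'
#' @param path file path.
#' @param roi_name ROI to extract from an RT-STRUCT (ignored for JSON).
#' @return a `contour_structure`.
#' @export
read_contours <- function(path, roi_name = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_json_contours(path)
  } else {
    read_rtstruct(path, roi_name)
  }
}
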