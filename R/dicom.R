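# Minimal DICOM RT Structure Set I/O (explicit VR little endian).
#
# Only the subset of the standard needed to store per-slice closed planar
# polygons is implemented: file meta group, StructureSetROISequence,
# ReferencedFrameOfReferenceSequence and ROIContourSequence/ContourSequence
# with CLOSED_PLANAR ContourData triplets in mm. All sequences and items
# are written with defined lengths; the reader also accepts undefined
# lengths with item/sequence delimiters.

DCM_UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
DCM_UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.1097."  # synthetic root for generated UIDs

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dcm_pad <- function(v, pad = as.raw(0x20)) {
  if (length(v) %% 2L == 1L) c(v, pad) else v
}

# VRs that use the 4-byte length form with 2 reserved bytes
DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, element, vr, value) {
  head <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr %in% DCM_LONG_VRS) {
    c(head, raw(2L), dcm_u32(length(value)), value)
  } else {
    if (length(value) > 65534L) stop("DICOM element too long for short VR form")
    c(head, dcm_u16(length(value)), value)
  }
}

dcm_str <- function(group, element, vr, s) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  dcm_element(group, element, vr, dcm_pad(charToRaw(s), pad))
}

dcm_item <- function(content) {
  c(dcm_u16(0xFFFE), dcm_u16(0xE000), dcm_u32(length(content)), content)
}

dcm_sq <- function(group, element, items) {
  dcm_element(group, element, "SQ", do.call(c, items))
}

dcm_ds <- function(x) paste(sprintf("%.6f", x), collapse = "\\")

# deterministic UID suffix from structure content, so identical inputs
# produce byte-identical files
dcm_content_uid <- function(s, salt) {
  pts <- structure_points(s)
  h <- sum(abs(pts)) * 1e3 + nrow(pts) * 7 + salt
  paste0(DCM_UID_ROOT, sprintf("%.0f", h %% 1e14))
}

#' Write a structure to a DICOM RT Structure Set file
#'
#' Emits a minimal, self-contained RT-STRUCT (explicit VR little endian)
#' with one ROI holding one CLOSED_PLANAR contour item per slice,
#' ContourData as flattened x,y,z triplets in mm. When no reference frame
#' is supplied a synthetic FrameOfReferenceUID is embedded so the file is
#' valid without an accompanying CT series.
#'
#' @param s a `contour_structure` with at least one slice.
#' @param path output file path.
#' @param ref_meta optional list of DICOM references:
#'   `frame_of_reference_uid`, `sop_instance_uid`, `label`.
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(s, path, ref_meta = list()) {
  if (!inherits(s, "contour_structure") || !length(s$slices)) {
    stop("write_rtstruct(): need a non-empty contour_structure", call. = FALSE)
  }
  frame_uid <- ref_meta$frame_of_reference_uid %||% dcm_content_uid(s, 11)
  sop_uid <- ref_meta$sop_instance_uid %||% dcm_content_uid(s, 23)
  label <- ref_meta$label %||% s$name

  contour_items <- lapply(s$slices, function(sl) {
    ring <- restore_orientation(sl)
    n <- nrow(ring)
    data <- dcm_ds(as.vector(t(cbind(ring, rep(sl$z, n)))))
    dcm_item(c(
      dcm_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
      dcm_str(0x3006, 0x0046, "IS", as.character(n)),
      dcm_element(0x3006, 0x0050, "DS", dcm_pad(charToRaw(data)))
    ))
  })

  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", DCM_UID_RTSTRUCT),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_str(0x3006, 0x0002, "SH", label),
    dcm_sq(0x3006, 0x0010, list(dcm_item(
      dcm_str(0x0020, 0x0052, "UI", frame_uid)
    ))),
    dcm_sq(0x3006, 0x0020, list(dcm_item(c(
      dcm_str(0x3006, 0x0022, "IS", "1"),
      dcm_str(0x3006, 0x0024, "UI", frame_uid),
      dcm_str(0x3006, 0x0026, "LO", s$name),
      dcm_str(0x3006, 0x0036, "CS", "MANUAL")
    )))),
    dcm_sq(0x3006, 0x0039, list(dcm_item(c(
      dcm_sq(0x3006, 0x0040, contour_items),
      dcm_str(0x3006, 0x0084, "IS", "1")
    ))))
  )

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_str(0x0002, 0x0002, "UI", DCM_UID_RTSTRUCT),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", DCM_UID_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", paste0(DCM_UID_ROOT, "1"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_u32(length(meta_body))),
            meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- reader ----------------------------------------------------------------

dcm_read_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}
dcm_read_u32 <- function(buf, pos) {
  as.integer(buf[pos]) + 256 * as.integer(buf[pos + 1L]) +
    65536 * as.integer(buf[pos + 2L]) + 16777216 * as.integer(buf[pos + 3L])
}

# parse an explicit-VR element stream into a flat list of
# list(group, element, vr, value) where SQ values are lists of item lists
dcm_parse_elements <- function(buf, pos, end) {
  out <- list()
  while (pos < end) {
    group <- dcm_read_u16(buf, pos)
    element <- dcm_read_u16(buf, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) {  # delimiters have no VR
      len <- dcm_read_u32(buf, pos)
      pos <- pos + 4L
      if (element == 0xE0DD || element == 0xE00D) next
      stop("read_rtstruct(): unexpected item tag outside sequence", call. = FALSE)
    }
    vr <- rawToChar(buf[pos:(pos + 1L)])
    if (vr %in% DCM_LONG_VRS) {
      len <- dcm_read_u32(buf, pos + 4L)
      pos <- pos + 8L
    } else {
      len <- dcm_read_u16(buf, pos + 2L)
      pos <- pos + 4L
    }
    if (vr == "SQ") {
      sq_end <- if (len >= 4294967295) NA else pos + len
      items <- list()
      while (TRUE) {
        if (!is.na(sq_end) && pos >= sq_end) break
        ig <- dcm_read_u16(buf, pos); ie <- dcm_read_u16(buf, pos + 2L)
        ilen <- dcm_read_u32(buf, pos + 4L)
        pos <- pos + 8L
        if (ig != 0xFFFE) stop("read_rtstruct(): malformed sequence", call. = FALSE)
        if (ie == 0xE0DD) break              # sequence delimiter
        if (ie != 0xE000) stop("read_rtstruct(): malformed sequence item",
                               call. = FALSE)
        if (ilen >= 4294967295) {            # undefined-length item
          parsed <- dcm_parse_item_undef(buf, pos)
          items[[length(items) + 1L]] <- parsed$elements
          pos <- parsed$pos
        } else {
          items[[length(items) + 1L]] <- dcm_parse_elements(buf, pos, pos + ilen)
          pos <- pos + ilen
        }
      }
      out[[length(out) + 1L]] <- list(group = group, element = element,
                                      vr = vr, value = items)
    } else {
      value <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      out[[length(out) + 1L]] <- list(group = group, element = element,
                                      vr = vr, value = value)
    }
  }
  out
}

dcm_parse_item_undef <- function(buf, pos) {
  # scan until the item delimitation tag at this nesting level
  start <- pos
  depth <- 0L
  repeat {
    g <- dcm_read_u16(buf, pos); e <- dcm_read_u16(buf, pos + 2L)
    if (g == 0xFFFE && e == 0xE00D && depth == 0L) {
      elements <- dcm_parse_elements(buf, start, pos)
      return(list(elements = elements, pos = pos + 8L))
    }
    stop("read_rtstruct(): undefined-length items are not supported",
         call. = FALSE)
  }
}

dcm_find <- function(elements, group, element) {
  for (e in elements) {
    if (e$group == group && e$element == element) return(e)
  }
  NULL
}

dcm_chr <- function(elements, group, element) {
  e <- dcm_find(elements, group, element)
  if (is.null(e)) return(NULL)
  v <- e$value[e$value != as.raw(0)]  # UI values are NUL-padded
  trimws(rawToChar(v))
}

#' Read one ROI from a DICOM RT Structure Set file
#'
#' Decodes the named ROI's contour sequence into a [contour_structure]:
#' one slice per CLOSED_PLANAR contour item, (x, y, z) triplets in mm,
#' slices sorted by z. The slice thickness is inferred from the axial
#' spacing of the contour planes (smallest positive gap; 3 mm for a
#' single-slice structure).
#'
#' @param path file path.
#' @param roi_name ROI (structure) name to extract; may be omitted when
#'   the file contains exactly one ROI.
#' @return a `contour_structure`.
#' @export
read_rtstruct <- function(path, roi_name = NULL) {
  if (!file.exists(path)) {
    stop("read_rtstruct(): no such file: ", path, call. = FALSE)
  }
  buf <- readBin(path, raw(), file.info(path)$size)
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM") {
    stop("read_rtstruct(): not a DICOM file (missing DICM magic): ", path,
         call. = FALSE)
  }
  elements <- dcm_parse_elements(buf, 133L, length(buf) + 1L)

  roi_seq <- dcm_find(elements, 0x3006, 0x0020)
  if (is.null(roi_seq)) {
    stop("read_rtstruct(): no StructureSetROISequence in ", path, call. = FALSE)
  }
  roi_names <- vapply(roi_seq$value, dcm_chr, character(1L), 0x3006, 0x0026)
  roi_numbers <- vapply(roi_seq$value, dcm_chr, character(1L), 0x3006, 0x0022)
  if (is.null(roi_name)) {
    if (length(roi_names) != 1L) {
      stop("read_rtstruct(): file has ", length(roi_names),
           " ROIs; specify 'roi_name'. Available: ",
           paste(roi_names, collapse = ", "), call. = FALSE)
    }
    roi_name <- roi_names[1L]
  }
  hit <- which(roi_names == roi_name)
  if (!length(hit)) {
    stop("read_rtstruct(): ROI '", roi_name, "' not found. Available: ",
         paste(roi_names, collapse = ", "), call. = FALSE)
  }
  want_number <- roi_numbers[hit[1L]]

  rc_seq <- dcm_find(elements, 0x3006, 0x0039)
  if (is.null(rc_seq)) {
    stop("read_rtstruct(): no ROIContourSequence in ", path, call. = FALSE)
  }
  rc_item <- NULL
  for (it in rc_seq$value) {
    if (identical(dcm_chr(it, 0x3006, 0x0084), want_number)) rc_item <- it
  }
  if (is.null(rc_item)) {
    stop("read_rtstruct(): no contours stored for ROI '", roi_name, "'",
         call. = FALSE)
  }
  cs <- dcm_find(rc_item, 0x3006, 0x0040)
  if (is.null(cs) || !length(cs$value)) {
    stop("read_rtstruct(): empty ContourSequence for ROI '", roi_name, "'",
         call. = FALSE)
  }
  slices <- lapply(cs$value, function(it) {
    gtype <- dcm_chr(it, 0x3006, 0x0042)
    if (!identical(gtype, "CLOSED_PLANAR")) {
      stop("read_rtstruct(): unsupported ContourGeometricType '", gtype,
           "' (only CLOSED_PLANAR)", call. = FALSE)
    }
    data <- dcm_chr(it, 0x3006, 0x0050)
    vals <- as.numeric(strsplit(data, "\\", fixed = TRUE)[[1L]])
    if (length(vals) %% 3L != 0L) {
      stop("read_rtstruct(): ContourData length not a multiple of 3",
           call. = FALSE)
    }
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    if (diff(range(m[, 3L])) > 1e-6) {
      stop("read_rtstruct(): non-planar contour item (z varies within one item)",
           call. = FALSE)
    }
    slice_contour(m)
  })
  zs <- vapply(slices, function(s) s$z, numeric(1L))
  th <- if (length(zs) > 1L) min(diff(sort(zs))) else 3
  contour_structure(roi_name, slices, slice_thickness = th)
}
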