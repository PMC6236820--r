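## Minimal DICOM support: explicit VR little endian only, axis-aligned
## geometry, the handful of modules needed for RT-DOSE volumes and RT-STRUCT
## planar contours. Readers reject other transfer syntaxes. Sequences are
## written with undefined lengths and item delimiters; the reader accepts
## both defined and undefined lengths.

TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
raw_undef_len <- as.raw(c(0xFF, 0xFF, 0xFF, 0xFF))

read_u16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1)], "integer", size = 2, signed = FALSE, endian = "little")
}
read_u32 <- function(buf, pos) {
  v <- readBin(buf[pos:(pos + 3)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else as.numeric(v)
}

dcm_header <- function(group, element, vr, length) {
  hdr <- c(raw_u16(group), raw_u16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) c(hdr, raw(2), raw_u32(length)) else c(hdr, raw_u16(length))
}

dcm_string <- function(group, element, vr, value) {
  b <- charToRaw(paste(value, collapse = "\\"))
  if (length(b) %% 2L == 1L) b <- c(b, if (vr == "UI") raw(1) else charToRaw(" "))
  c(dcm_header(group, element, vr, length(b)), b)
}

dcm_ds <- function(group, element, values) {
  dcm_string(group, element, "DS", paste(sprintf("%.10g", values), collapse = "\\"))
}
dcm_is <- function(group, element, values) {
  dcm_string(group, element, "IS", paste(sprintf("%d", as.integer(values)), collapse = "\\"))
}
dcm_us <- function(group, element, values) {
  b <- raw_u16(values)
  c(dcm_header(group, element, "US", length(b)), b)
}
dcm_ow <- function(group, element, bytes) {
  c(dcm_header(group, element, "OW", length(bytes)), bytes)
}
dcm_sq <- function(group, element, items) {
  body <- raw(0)
  for (it in items) {
    body <- c(body, raw_u16(0xFFFE), raw_u16(0xE000), raw_undef_len, it,
              raw_u16(0xFFFE), raw_u16(0xE00D), raw_u32(0))
  }
  c(raw_u16(group), raw_u16(element), charToRaw("SQ"), raw(2), raw_undef_len,
    body, raw_u16(0xFFFE), raw_u16(0xE0DD), raw_u32(0))
}

dcm_file <- function(sop_class, sop_instance, dataset) {
  meta <- c(
    c(dcm_header(0x0002, 0x0001, "OB", 2), as.raw(c(0x00, 0x01))),
    dcm_string(0x0002, 0x0002, "UI", sop_class),
    dcm_string(0x0002, 0x0003, "UI", sop_instance),
    dcm_string(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_ELE),
    dcm_string(0x0002, 0x0012, "UI", "2.25.999")
  )
  grouplen <- c(dcm_header(0x0002, 0x0000, "UL", 4), raw_u32(length(meta)))
  c(raw(128), charToRaw("DICM"), grouplen, meta, dataset)
}

## ---- parsing --------------------------------------------------------------

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# rawToChar with trailing padding (space or NUL) removed; DICOM string
# values are space/NUL padded to even length.
raw_to_string <- function(bytes) {
  while (length(bytes) && (bytes[length(bytes)] == as.raw(0) ||
                           bytes[length(bytes)] == as.raw(0x20))) {
    bytes <- bytes[-length(bytes)]
  }
  rawToChar(bytes)
}

parse_value <- function(vr, bytes) {
  if (length(bytes) == 0) return(NULL)
  switch(vr,
    DS = as.numeric(strsplit(trimws(raw_to_string(bytes)), "\\", fixed = TRUE)[[1]]),
    IS = as.integer(strsplit(trimws(raw_to_string(bytes)), "\\", fixed = TRUE)[[1]]),
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4, endian = "little"),
    FL = readBin(bytes, "double", n = length(bytes) / 4, size = 4, endian = "little"),
    FD = readBin(bytes, "double", n = length(bytes) / 8, size = 8, endian = "little"),
    UI = raw_to_string(bytes),
    OB = bytes, OW = bytes,
    raw_to_string(bytes)  # LO, SH, CS, PN, ST, DA, TM, ...
  )
}

# Parse one dataset from buf[pos..end]; stops at end or at an item
# delimitation tag (returned in `stopped_at`). Returns elements keyed
# "GGGG,EEEE" -> list(vr, value).
parse_dataset <- function(buf, pos, end) {
  elements <- list()
  while (pos <= end) {
    group <- read_u16(buf, pos); element <- read_u16(buf, pos + 2); pos <- pos + 4
    if (group == 0xFFFE) {
      len <- read_u32(buf, pos); pos <- pos + 4
      if (element == 0xE00D || element == 0xE0DD) {
        return(list(elements = elements, pos = pos, delimiter = element))
      }
      stop("malformed DICOM: unexpected item tag outside a sequence")
    }
    vr <- rawToChar(buf[pos:(pos + 1)]); pos <- pos + 2
    if (vr %in% LONG_VRS) {
      pos <- pos + 2
      len <- read_u32(buf, pos); pos <- pos + 4
    } else {
      len <- read_u16(buf, pos); pos <- pos + 2
    }
    if (vr == "SQ") {
      sq_end <- if (len == 4294967295) end else pos + len - 1
      items <- list()
      repeat {
        if (pos > sq_end) break
        g2 <- read_u16(buf, pos); e2 <- read_u16(buf, pos + 2)
        ilen <- read_u32(buf, pos + 4); pos <- pos + 8
        if (g2 == 0xFFFE && e2 == 0xE0DD) break
        if (!(g2 == 0xFFFE && e2 == 0xE000)) stop("malformed DICOM: expected sequence item")
        item_end <- if (ilen == 4294967295) sq_end else pos + ilen - 1
        res <- parse_dataset(buf, pos, item_end)
        items[[length(items) + 1L]] <- res$elements
        pos <- res$pos
        if (ilen != 4294967295 && is.null(res$delimiter)) pos <- item_end + 1
      }
      elements[[tag_key(group, element)]] <- list(vr = "SQ", value = items)
    } else {
      val <- if (len > 0) buf[pos:(pos + len - 1)] else raw(0)
      elements[[tag_key(group, element)]] <- list(vr = vr, value = parse_value(vr, val))
      pos <- pos + len
    }
  }
  list(elements = elements, pos = pos, delimiter = NULL)
}

read_dicom_dataset <- function(path) {
  buf <- readBin(path, raw(), file.info(path)$size)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM") {
    stop("malformed DICOM: missing DICM magic")
  }
  pos <- 133
  # file meta group (always explicit LE); find transfer syntax
  ts <- NULL
  repeat {
    group <- read_u16(buf, pos)
    if (group != 0x0002) break
    element <- read_u16(buf, pos + 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(buf, pos + 8); body <- pos + 12
    } else {
      len <- read_u16(buf, pos + 6); body <- pos + 8
    }
    if (element == 0x0010) ts <- parse_value("UI", buf[body:(body + len - 1)])
    pos <- body + len
  }
  if (is.null(ts) || ts != TRANSFER_SYNTAX_ELE) {
    stop("unsupported transfer syntax: only explicit VR little endian is supported")
  }
  parse_dataset(buf, pos, length(buf))$elements
}

ds_get <- function(elements, key, default = NULL) {
  el <- elements[[key]]
  if (is.null(el)) default else el$value
}

## ---- RT-DOSE --------------------------------------------------------------

#' Write a DICOM RT-DOSE file
#'
#' Serialises a dose grid as a multi-frame DICOM RT-DOSE object (explicit VR
#' little endian, axis-aligned identity orientation, 32-bit pixels with a
#' dose-grid scaling factor). Intended for fixtures and interchange with
#' planning systems that accept axis-aligned grids.
#'
#' @param dose A [dose_grid()].
#' @param path Output path.
#' @param sop_instance_uid SOP Instance UID to embed (stable default keeps
#'   output byte-reproducible).
#' @return The path, invisibly.
#' @export
write_rtdose <- function(dose, path, sop_instance_uid = "2.25.1") {
  stopifnot(inherits(dose, "dose_grid"))
  g <- dose$grid
  maxdose <- max(dose$dose)
  scaling <- if (maxdose > 0) maxdose / (2^31 - 2) else 1
  ints <- as.integer(round(dose$dose / scaling))
  offsets <- (seq_len(g$dims[3]) - 1) * g$spacing[3]
  dataset <- c(
    dcm_string(0x0008, 0x0016, "UI", SOP_RTDOSE),
    dcm_string(0x0008, 0x0018, "UI", sop_instance_uid),
    dcm_string(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_ds(0x0020, 0x0032, g$origin),
    dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    dcm_us(0x0028, 0x0002, 1),
    dcm_string(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_is(0x0028, 0x0008, g$dims[3]),
    dcm_us(0x0028, 0x0010, g$dims[2]),
    dcm_us(0x0028, 0x0011, g$dims[1]),
    dcm_ds(0x0028, 0x0030, c(g$spacing[2], g$spacing[1])),
    dcm_us(0x0028, 0x0100, 32),
    dcm_us(0x0028, 0x0101, 32),
    dcm_us(0x0028, 0x0102, 31),
    dcm_us(0x0028, 0x0103, 0),
    dcm_string(0x3004, 0x0002, "CS", "GY"),
    dcm_string(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_string(0x3004, 0x000A, "CS", "PLAN"),
    dcm_ds(0x3004, 0x000C, offsets),
    dcm_ds(0x3004, 0x000E, scaling),
    dcm_ow(0x7FE0, 0x0010, writeBin(ints, raw(), size = 4, endian = "little"))
  )
  writeBin(dcm_file(SOP_RTDOSE, sop_instance_uid, dataset), path)
  invisible(path)
}

#' Read a DICOM RT-DOSE file
#'
#' Voxel values are the stored integers times the dose-grid scaling factor,
#' in Gy; grid geometry comes from the position/spacing/frame-offset tags.
#' Only the identity orientation (rows along +y, columns along +x,
#' frames along +z) is supported.
#'
#' @param path Path to an RT-DOSE file (explicit VR little endian).
#' @param prescription Prescription dose in Gy(RBE) to attach (RT-DOSE files
#'   do not carry one; it normally comes from the cohort manifest).
#' @return A [dose_grid()].
#' @export
read_rtdose <- function(path, prescription) {
  el <- read_dicom_dataset(path)
  orient <- ds_get(el, "0020,0037")
  if (is.null(orient) || max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6) {
    stop("unsupported orientation: RT-DOSE must be axis-aligned identity")
  }
  scaling <- ds_get(el, "3004,000E")
  if (is.null(scaling)) stop("malformed dose: missing DoseGridScaling (3004,000E)")
  nx <- ds_get(el, "0028,0011"); ny <- ds_get(el, "0028,0010")
  nz <- ds_get(el, "0028,0008", 1L)
  origin <- ds_get(el, "0020,0032")
  ps <- ds_get(el, "0028,0030")
  offsets <- ds_get(el, "3004,000C")
  if (is.null(nx) || is.null(ny) || is.null(origin) || is.null(ps)) {
    stop("malformed dose: missing geometry tags")
  }
  dz <- if (nz > 1) {
    steps <- diff(offsets)
    if (max(abs(steps - steps[1])) > 1e-6) stop("malformed dose: non-uniform frame offsets")
    steps[1]
  } else 1
  bits <- ds_get(el, "0028,0100", 32)
  if (bits != 32) stop("malformed dose: only 32-bit dose pixels are supported")
  pix <- ds_get(el, "7FE0,0010")
  ints <- readBin(pix, "integer", n = as.integer(nx) * ny * nz, size = 4, endian = "little")
  grid <- voxel_grid(origin, c(ps[2], ps[1], dz), c(nx, ny, nz))
  dose_grid(grid, as.numeric(ints) * scaling, prescription)
}

## ---- RT-STRUCT ------------------------------------------------------------

#' Map clinical structure names to model roles
#'
#' Case-insensitive regular expressions resolving the ROIs of a structure
#' set to the roles the model needs. Every role must match exactly one ROI in
#' a given structure set.
#'
#' @param ... Named patterns, e.g. `ptv = "^ptv"`,
#'   `lung_left = "lung[_ ]*l"`.
#' @return A named character vector of class `structure_name_map`.
#' @export
structure_name_map <- function(...) {
  pats <- c(...)
  if (length(pats) == 0L) {
    pats <- c(ptv = "^ptv", lung_left = "^(lung[_ ]*l|left[_ ]*lung)",
              lung_right = "^(lung[_ ]*r|right[_ ]*lung)")
  }
  if (is.null(names(pats)) || any(!nzchar(names(pats)))) {
    stop("structure_name_map: every pattern must be named with its role")
  }
  structure(pats, class = "structure_name_map")
}

#' Rasterise planar contours onto a voxel grid
#'
#' A voxel is inside iff its center lies inside the contour polygon on the
#' nearest slice, combined across overlapping contours by the even-odd rule
#' (so holes are honoured). Deterministic on every platform.
#'
#' @param contours List of numeric matrices (n x 3, mm); each must be planar
#'   in z.
#' @param grid Target [voxel_grid()].
#' @return A [binary_mask()].
#' @export
rasterize_contours <- function(contours, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- array(FALSE, dim = grid$dims)
  ax <- grid_axes(grid)
  for (ct in contours) {
    ct <- as.matrix(ct)
    if (ncol(ct) != 3L || nrow(ct) < 3L) stop("rasterize_contours: contours must be n x 3 with n >= 3")
    if (diff(range(ct[, 3])) > 1e-3) {
      stop("unsupported geometry: contour is not planar in z")
    }
    k <- round((mean(ct[, 3]) - grid$origin[3]) / grid$spacing[3]) + 1
    if (k < 1 || k > grid$dims[3]) next
    centers <- expand.grid(x = ax[[1]], y = ax[[2]])
    inside <- .points_in_polygon(centers$x, centers$y, ct[, 1], ct[, 2])
    occ[, , k] <- xor(occ[, , k], matrix(inside, nrow = grid$dims[1]))
  }
  binary_mask(grid, occ)
}

#' Write a DICOM RT-STRUCT file (synthetic)
#'
#' Serialises named sets of closed planar contours as an RT-STRUCT object.
#' Used to build synthetic structure-set fixtures; it writes only the ROI and
#' contour modules needed by [read_rtstruct()].
#'
#' @param structures Named list; each entry a list of n x 3 contour matrices
#'   (mm, planar in z).
#' @param path Output path.
#' @param sop_instance_uid SOP Instance UID to embed.
#' @return The path, invisibly.
#' @export
write_rtstruct <- function(structures, path, sop_instance_uid = "2.25.2") {
  if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
    stop("write_rtstruct: structures must be a named list")
  }
  roi_items <- lapply(seq_along(structures), function(i) {
    c(dcm_is(0x3006, 0x0022, i),
      dcm_string(0x3006, 0x0024, "UI", "2.25.1000"),
      dcm_string(0x3006, 0x0026, "LO", names(structures)[i]))
  })
  contour_items <- lapply(seq_along(structures), function(i) {
    cts <- lapply(structures[[i]], function(ct) {
      ct <- as.matrix(ct)
      c(dcm_string(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_is(0x3006, 0x0046, nrow(ct)),
        dcm_ds(0x3006, 0x0050, as.numeric(t(ct))))
    })
    c(dcm_sq(0x3006, 0x0040, cts), dcm_is(0x3006, 0x0084, i))
  })
  dataset <- c(
    dcm_string(0x0008, 0x0016, "UI", SOP_RTSTRUCT),
    dcm_string(0x0008, 0x0018, "UI", sop_instance_uid),
    dcm_string(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_string(0x3006, 0x0002, "SH", "synthetic"),
    dcm_sq(0x3006, 0x0020, roi_items),
    dcm_sq(0x3006, 0x0039, contour_items)
  )
  writeBin(dcm_file(SOP_RTSTRUCT, sop_instance_uid, dataset), path)
  invisible(path)
}

#' Read structures from a DICOM RT-STRUCT file
#'
#' Resolves the requested roles through a [structure_name_map()] and
#' rasterises each ROI's closed planar contours onto the supplied grid with
#' the even-odd voxel-center rule (see [rasterize_contours()]).
#'
#' @param path Path to an RT-STRUCT file (explicit VR little endian).
#' @param grid Target [voxel_grid()].
#' @param name_map A [structure_name_map()]; only its roles are returned.
#' @return Named list of [binary_mask()]s, one per role.
#' @export
read_rtstruct <- function(path, grid, name_map = structure_name_map()) {
  stopifnot(inherits(grid, "voxel_grid"))
  el <- read_dicom_dataset(path)
  rois <- ds_get(el, "3006,0020")
  if (is.null(rois)) stop("malformed RT-STRUCT: missing StructureSetROISequence")
  roi_names <- vapply(rois, function(it) as.character(ds_get(it, "3006,0026", "")), character(1))
  roi_numbers <- vapply(rois, function(it) as.integer(ds_get(it, "3006,0022", NA_integer_)), integer(1))
  contours_by_roi <- list()
  for (it in ds_get(el, "3006,0039", list())) {
    num <- as.character(ds_get(it, "3006,0084"))
    cts <- lapply(ds_get(it, "3006,0040", list()), function(c_it) {
      gtype <- ds_get(c_it, "3006,0042", "CLOSED_PLANAR")
      if (!identical(gtype, "CLOSED_PLANAR")) {
        stop(sprintf("unsupported geometry: contour type %s (only CLOSED_PLANAR)", gtype))
      }
      matrix(ds_get(c_it, "3006,0050"), ncol = 3, byrow = TRUE)
    })
    contours_by_roi[[num]] <- cts
  }
  out <- list()
  for (role in names(name_map)) {
    hit <- grep(name_map[[role]], roi_names, ignore.case = TRUE)
    if (length(hit) == 0L) {
      stop(sprintf("structure not found: no ROI matches role '%s' (pattern '%s')",
                   role, name_map[[role]]))
    }
    if (length(hit) > 1L) {
      stop(sprintf("ambiguous structure: role '%s' matches ROIs: %s",
                   role, paste(roi_names[hit], collapse = ", ")))
    }
    cts <- contours_by_roi[[as.character(roi_numbers[hit])]]
    if (is.null(cts)) stop(sprintf("structure not found: ROI '%s' has no contours", roi_names[hit]))
    out[[role]] <- rasterize_contours(cts, grid)
  }
  out
}
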