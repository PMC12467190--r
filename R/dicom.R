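# Minimal single-frame DICOM reader/writer (explicit VR little endian,
# uncompressed 16-bit monochrome). Covers exactly what paired CT slice
# pipelines need: Rows/Columns, PixelSpacing, RescaleSlope/Intercept,
# PatientID, InstanceNumber, PixelData. Not a general DICOM library.

DCM_TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1" # explicit VR little endian
DCM_SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# pad string values to even length; UI pads with NUL, text VRs with space
dcm_strval <- function(s, vr) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) {
    r <- c(r, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  r
}

dcm_element <- function(group, element, vr, value) {
  raw_value <- if (is.raw(value)) value else dcm_strval(value, vr)
  head <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), dcm_uint32(length(raw_value)), raw_value)
  } else {
    if (length(raw_value) > 65534L) stop("value too long for short-form VR")
    c(head, dcm_uint16(length(raw_value)), raw_value)
  }
}

#' Write one CT slice as a DICOM file
#'
#' Stores pixels as signed 16-bit integers with the given rescale so that
#' `stored * slope + intercept` reproduces the HU grid up to quantization
#' `slope / 2`.
#'
#' @param img a [ct_image()].
#' @param path output file path.
#' @param slope,intercept DICOM rescale parameters used for storage.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(img, path, slope = 1, intercept = -1024) {
  stopifnot(inherits(img, "ct_image"))
  stored <- hu_to_stored(img$pixels, slope, intercept)
  if (any(stored < -32768 | stored > 32767)) {
    stop("stored values exceed the signed 16-bit range; adjust slope/intercept",
         call. = FALSE)
  }
  m <- nrow(img$pixels); n <- ncol(img$pixels)

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", DCM_SOP_CLASS_CT),
    dcm_element(0x0002, 0x0003, "UI",
                sprintf("1.2.826.0.1.3680043.9999.%d", img$slice_index)),
    dcm_element(0x0002, 0x0010, "UI", DCM_TRANSFER_SYNTAX_ELE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta))), meta)

  # pixel data: column-major R matrix -> DICOM row-major
  pix_raw <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

  body <- c(
    dcm_element(0x0008, 0x0016, "UI", DCM_SOP_CLASS_CT),
    dcm_element(0x0008, 0x0018, "UI",
                sprintf("1.2.826.0.1.3680043.9999.%d", img$slice_index)),
    dcm_element(0x0010, 0x0020, "LO", img$patient_id),
    dcm_element(0x0020, 0x0013, "IS", as.character(img$slice_index)),
    dcm_element(0x0028, 0x0002, "US", dcm_uint16(1L)),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", dcm_uint16(m)),
    dcm_element(0x0028, 0x0011, "US", dcm_uint16(n)),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%.10g\\%.10g", img$pixel_spacing[1], img$pixel_spacing[2])),
    dcm_element(0x0028, 0x0100, "US", dcm_uint16(16L)),
    dcm_element(0x0028, 0x0101, "US", dcm_uint16(16L)),
    dcm_element(0x0028, 0x0102, "US", dcm_uint16(15L)),
    dcm_element(0x0028, 0x0103, "US", dcm_uint16(1L)),
    dcm_element(0x0028, 0x1052, "DS", sprintf("%.10g", intercept)),
    dcm_element(0x0028, 0x1053, "DS", sprintf("%.10g", slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# cursor-based parser over a raw vector
dcm_parse <- function(raw_bytes, path) {
  if (length(raw_bytes) < 132L ||
      rawToChar(raw_bytes[129:132]) != "DICM") {
    stop(sprintf("'%s' is not a DICOM file (missing DICM marker)", path),
         call. = FALSE)
  }
  pos <- 133L
  n_total <- length(raw_bytes)
  elems <- list()
  rd_u16 <- function(at) readBin(raw_bytes[at:(at + 1L)], "integer",
                                 size = 2, endian = "little", signed = FALSE)
  rd_u32 <- function(at) readBin(raw_bytes[at:(at + 3L)], "integer",
                                 size = 4, endian = "little")
  while (pos + 7L <= n_total) {
    group <- rd_u16(pos); element <- rd_u16(pos + 2L)
    vr <- rawToChar(raw_bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rd_u32(pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- rd_u16(pos + 6L)
      val_at <- pos + 8L
    }
    value <- if (len > 0L) raw_bytes[val_at:(val_at + len - 1L)] else raw(0L)
    key <- sprintf("%04X,%04X", group, element)
    elems[[key]] <- list(vr = vr, value = value)
    pos <- val_at + len
  }
  elems
}

dcm_get_str <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$value[e$value != as.raw(0L)]))
}

dcm_get_u16 <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$value, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Read one DICOM CT slice
#'
#' Parses a single-frame, uncompressed, explicit-VR little-endian DICOM file
#' and applies the rescale tags to return a [ct_image()] in HU.
#'
#' @param path file path.
#' @return A [ct_image()]; the dose tag is not stored in DICOM and defaults
#'   to `"HQ"` (series manifests carry it, see [write_ct_series()]).
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path),
                               call. = FALSE)
  elems <- dcm_parse(readBin(path, "raw", file.info(path)$size), path)

  slope_s <- dcm_get_str(elems, "0028,1053")
  intercept_s <- dcm_get_str(elems, "0028,1052")
  if (is.null(slope_s)) {
    stop("missing RescaleSlope tag (0028,1053)", call. = FALSE)
  }
  if (is.null(intercept_s)) {
    stop("missing RescaleIntercept tag (0028,1052)", call. = FALSE)
  }
  m <- dcm_get_u16(elems, "0028,0010")
  n <- dcm_get_u16(elems, "0028,0011")
  if (is.null(m) || is.null(n)) {
    stop("missing Rows (0028,0010) or Columns (0028,0011) tag", call. = FALSE)
  }
  bits <- dcm_get_u16(elems, "0028,0100")
  if (!is.null(bits) && bits != 16L) {
    stop(sprintf("only 16-bit pixel data is supported (BitsAllocated = %d)", bits),
         call. = FALSE)
  }
  signed <- isTRUE(dcm_get_u16(elems, "0028,0103") == 1L)
  pix_el <- elems[["7FE0,0010"]]
  if (is.null(pix_el)) stop("missing PixelData tag (7FE0,0010)", call. = FALSE)
  stored <- readBin(pix_el$value, "integer", n = m * n, size = 2,
                    endian = "little", signed = signed)
  # DICOM is row-major
  stored <- t(matrix(stored, nrow = n, ncol = m))

  spacing_s <- dcm_get_str(elems, "0028,0030")
  spacing <- if (is.null(spacing_s)) c(1, 1) else
    as.numeric(strsplit(spacing_s, "\\\\")[[1]])
  idx_s <- dcm_get_str(elems, "0020,0013")
  pid <- dcm_get_str(elems, "0010,0020")

  ct_image(stored_to_hu(stored, as.numeric(slope_s), as.numeric(intercept_s)),
           pixel_spacing = spacing,
           patient_id = if (is.null(pid)) "anon" else pid,
           slice_index = if (is.null(idx_s)) 0L else as.integer(idx_s),
           dose_tag = "HQ")
}

#' Write a list of CT slices as a DICOM series
#'
#' One file per slice (`slice_<index>.dcm`) plus a JSON sidecar
#' (`manifest.json`) recording patient id, slice order and dose tags. All
#' slices must share geometry.
#'
#' @param images list of [ct_image()] with identical dimensions and spacing.
#' @param dir output directory (created if absent).
#' @inheritParams write_dicom
#' @return `dir`, invisibly.
#' @export
write_ct_series <- function(images, dir, slope = 1, intercept = -1024) {
  stopifnot(length(images) > 0L, all(vapply(images, inherits, TRUE, "ct_image")))
  dims <- vapply(images, function(x) dim(x$pixels), integer(2))
  sp <- vapply(images, function(x) x$pixel_spacing, numeric(2))
  if (any(dims != dims[, 1]) || any(abs(sp - sp[, 1]) > 1e-9)) {
    stop("all images in a series must share dimensions and pixel spacing",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (img in images) {
    write_dicom(img, file.path(dir, sprintf("slice_%04d.dcm", img$slice_index)),
                slope = slope, intercept = intercept)
  }
  manifest <- list(
    patient_id = images[[1]]$patient_id,
    pixel_spacing = images[[1]]$pixel_spacing,
    slices = data.frame(
      slice_index = vapply(images, `[[`, 0L, "slice_index"),
      dose_tag = vapply(images, `[[`, "", "dose_tag"),
      file = vapply(images, function(x) sprintf("slice_%04d.dcm", x$slice_index), "")
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a DICOM series from a directory
#'
#' Reads every `*.dcm` file, restores dose tags from `manifest.json` when
#' present, and returns slices ordered by slice index regardless of file
#' naming.
#'
#' @param dir directory containing the series.
#' @return List of [ct_image()] ordered by `slice_index`; empty (with a
#'   warning) if the directory contains no DICOM files.
#' @export
read_ct_series <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory '%s' does not exist", dir),
                             call. = FALSE)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) {
    warning(sprintf("no DICOM files found in '%s'", dir), call. = FALSE)
    return(list())
  }
  images <- lapply(files, read_dicom)
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    tags <- stats::setNames(man$slices$dose_tag, man$slices$slice_index)
    images <- lapply(images, function(img) {
      tag <- tags[as.character(img$slice_index)]
      if (!is.na(tag)) img$dose_tag <- unname(tag)
      img
    })
  }
  images[order(vapply(images, `[[`, 0L, "slice_index"))]
}

#' Export an 8-bit image as PNG for inspection
#'
#' @param img8 an [image8()].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_png8 <- function(img8, path) {
  stopifnot(inherits(img8, "image8"))
  png::writePNG(img8$pixels / 255, path)
  invisible(path)
}
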