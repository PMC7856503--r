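# Minimal DICOM RT Image support.
#
# Portal-dose exports from TrueBeam-class imagers are plain single-frame
# DICOM RT Image objects in Explicit VR Little Endian. Only that transfer
# syntax and the handful of data elements a dosimetric reader needs are
# supported: pixel grid, rescale slope/intercept, imager pixel spacing, the
# radiation-machine distances (SAD, RT Image SID), meterset exposure and
# collimator angle. Sequences and compressed pixel data are out of scope.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
RTIMAGE_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.1"

# VRs whose value length is encoded as 2 reserved bytes + 4-byte uint32.
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a DICOM RT Image portal dose export
#'
#' Parses a single-frame Explicit-VR-Little-Endian DICOM RT Image and returns
#' a calibrated [portal_image()]: rescale slope and intercept are applied to
#' the stored values, and detector spacing, RT Image SID (source-to-imager
#' distance) and radiation machine SAD are taken from the object. Meterset
#' exposure becomes `mu` when present; a missing meterset only warns, because
#' all daily-QA quantities are ratios to a benchmark acquired at the same MU.
#'
#' @param path path to the DICOM file.
#' @return a [portal_image()] with `vendor_dialect = "dicom_rtimage"`.
#' @export
read_dicom_rtimage <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("DICOM file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stop_format("not a DICOM part-10 file (missing 'DICM' magic).")
  }
  elements <- parse_dicom_elements(raw)
  ts <- dicom_string(elements, "0002,0010")
  if (!is.null(ts) && ts != DICOM_EXPLICIT_LE) {
    stop_format(sprintf("unsupported transfer syntax '%s' (only Explicit VR Little Endian).", ts))
  }

  rows <- dicom_us(elements, "0028,0010")
  cols <- dicom_us(elements, "0028,0011")
  bits <- dicom_us(elements, "0028,0100") %||% 16L
  pixrep <- dicom_us(elements, "0028,0103") %||% 0L
  pixel_data <- elements[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pixel_data)) {
    stop_format("DICOM RT Image is missing Rows/Columns or PixelData.")
  }
  spacing <- dicom_ds(elements, "3002,0011")
  if (is.null(spacing)) {
    stop_format("DICOM RT Image is missing ImagePlanePixelSpacing (3002,0011).")
  }
  if (length(spacing) == 2 && abs(spacing[1] - spacing[2]) > 1e-6) {
    stop_format("anisotropic imager pixel spacing is not supported.")
  }
  sad <- dicom_ds(elements, "3002,0022")
  sid <- dicom_ds(elements, "3002,0026")
  if (is.null(sad) || is.null(sid)) {
    stop_format("DICOM RT Image is missing RadiationMachineSAD or RTImageSID.")
  }
  mu <- dicom_ds(elements, "3002,0032")
  if (is.null(mu)) {
    warn("DICOM RT Image has no MetersetExposure (3002,0032); MU left unset.")
    mu <- NA_real_
  }
  coll <- dicom_ds(elements, "300a,0120") %||% 0

  size <- if (bits == 16L) 2L else 1L
  n <- as.integer(rows) * as.integer(cols)
  if (length(pixel_data$value) < n * size) {
    stop_format("PixelData is shorter than Rows x Columns.")
  }
  stored <- readBin(pixel_data$value, "integer",
    n = n, size = size,
    signed = pixrep == 1L, endian = "little"
  )
  if (size == 2L && pixrep == 0L) stored <- ifelse(stored < 0, stored + 65536, stored)
  slope <- (dicom_ds(elements, "0028,1053") %||% 1)[1]
  intercept <- (dicom_ds(elements, "0028,1052") %||% 0)[1]
  # DICOM pixel data is row-major.
  px <- matrix(stored * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)
  if (min(px) < 0) px <- px - min(px)

  portal_image(
    pixels = px,
    pixel_spacing_detector = spacing[1],
    sdd = sid[1],
    sad = sad[1],
    mu = mu[1],
    modifier = "open",
    beam_label = dicom_string(elements, "3002,0020") %||% "6MV",
    collimator_angle = coll[1],
    vendor_dialect = "dicom_rtimage"
  )
}

# Walk the element stream, returning a named list keyed "gggg,eeee" of
# list(vr, value-raw). Stops cleanly at the end of the buffer.
parse_dicom_elements <- function(raw) {
  pos <- 133L
  out <- list()
  total <- length(raw)
  while (pos + 7L <= total) {
    group <- readBin(raw[pos:(pos + 1L)], "integer", size = 2, signed = FALSE, endian = "little")
    elem <- readBin(raw[(pos + 2L):(pos + 3L)], "integer", size = 2, signed = FALSE, endian = "little")
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop_format("implicit-VR or corrupt DICOM element stream.")
    }
    if (vr %in% LONG_VRS) {
      len <- readBin(raw[(pos + 8L):(pos + 11L)], "integer", size = 4, endian = "little")
      hdr <- 12L
    } else {
      len <- readBin(raw[(pos + 6L):(pos + 7L)], "integer", size = 2, signed = FALSE, endian = "little")
      hdr <- 8L
    }
    if (len < 0 || pos + hdr + len - 1L > total) {
      stop_format("truncated DICOM element.")
    }
    key <- sprintf("%04x,%04x", group, elem)
    value <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    out[[key]] <- list(vr = vr, value = value)
    pos <- pos + hdr + len
  }
  out
}

dicom_string <- function(elements, key) {
  el <- elements[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dicom_ds <- function(elements, key) {
  s <- dicom_string(elements, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(elements, key) {
  el <- elements[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", size = 2, signed = FALSE, endian = "little")[1]
}

#' Write a portal image as a minimal DICOM RT Image
#'
#' Emits a conformant-enough Explicit-VR-Little-Endian RT Image: file meta
#' group, SOP identifiers, the pixel module, imager geometry and meterset.
#' Pixels are stored as unsigned 16-bit after applying the inverse of
#' `slope`/`intercept` (stored = (value - intercept) / slope, rounded), so
#' integer-valued signals with slope 1 round-trip exactly. Used by the
#' synthetic module to exercise the DICOM reader; not a clinical archive
#' writer.
#'
#' @param image a [portal_image()].
#' @param path output path.
#' @param slope,intercept rescale applied on reading.
#' @param omit_spacing,omit_mu drop the corresponding tags (for testing
#'   malformed exports).
#' @return `path`, invisibly.
#' @export
write_dicom_rtimage <- function(image, path, slope = 1, intercept = 0,
                                omit_spacing = FALSE, omit_mu = FALSE) {
  stopifnot(inherits(image, "portal_image"))
  px <- image$pixels
  stored <- round((px - intercept) / slope)
  if (any(stored < 0) || any(stored > 65535)) {
    stop_input("stored pixel values fall outside the unsigned 16-bit range.")
  }
  # writeBin(size = 2) wants signed shorts; map the upper uint16 half down.
  v <- as.integer(t(stored))
  v[v >= 32768L] <- v[v >= 32768L] - 65536L
  stored_raw <- writeBin(v, raw(), size = 2, endian = "little")

  ds <- function(x) paste(formatC(x, format = "fg", digits = 10), collapse = "\\")
  body <- c(
    dicom_element(0x0008, 0x0016, "UI", charToRaw(RTIMAGE_SOP_CLASS)),
    dicom_element(0x0008, 0x0018, "UI", charToRaw(sprintf(
      "1.2.826.0.1.3680043.9.9999.%d.%d.%.0f", nrow(px), ncol(px), sum(stored) %% 1e6
    ))),
    dicom_element(0x0008, 0x0060, "CS", charToRaw("RTIMAGE")),
    dicom_element(0x0028, 0x0002, "US", writeBin(1L, raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0004, "CS", charToRaw("MONOCHROME2")),
    dicom_element(0x0028, 0x0010, "US", writeBin(nrow(px), raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0011, "US", writeBin(ncol(px), raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0100, "US", writeBin(16L, raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0101, "US", writeBin(16L, raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0102, "US", writeBin(15L, raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0103, "US", writeBin(0L, raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x1052, "DS", charToRaw(ds(intercept))),
    dicom_element(0x0028, 0x1053, "DS", charToRaw(ds(slope))),
    dicom_element(0x3002, 0x0020, "SH", charToRaw(image$beam_label)),
    if (!omit_spacing) {
      dicom_element(0x3002, 0x0011, "DS", charToRaw(ds(rep(image$pixel_spacing_detector, 2))))
    },
    dicom_element(0x3002, 0x0022, "DS", charToRaw(ds(image$sad))),
    dicom_element(0x3002, 0x0026, "DS", charToRaw(ds(image$sdd))),
    if (!omit_mu && !is.na(image$mu)) {
      dicom_element(0x3002, 0x0032, "DS", charToRaw(ds(image$mu)))
    },
    dicom_element(0x300a, 0x0120, "DS", charToRaw(ds(image$collimator_angle))),
    dicom_element(0x7fe0, 0x0010, "OW", stored_raw)
  )
  body <- do.call(c, body[!vapply(body, is.null, logical(1))])

  meta <- c(
    dicom_element(0x0002, 0x0002, "UI", charToRaw(RTIMAGE_SOP_CLASS)),
    dicom_element(0x0002, 0x0010, "UI", charToRaw(DICOM_EXPLICIT_LE))
  )
  meta <- do.call(c, meta)
  group_len <- dicom_element(0x0002, 0x0000, "UL", writeBin(length(meta), raw(), size = 4, endian = "little"))[[1]]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, body), con)
  invisible(path)
}

# One encoded element as a list holding a raw vector (NULL-able in callers).
dicom_element <- function(group, elem, vr, value) {
  if (length(value) %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value <- c(value, pad)
  }
  hdr <- c(
    writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
    charToRaw(vr)
  )
  if (vr %in% LONG_VRS) {
    hdr <- c(hdr, raw(2), writeBin(length(value), raw(), size = 4, endian = "little"))
  } else {
    hdr <- c(hdr, writeBin(length(value), raw(), size = 2, endian = "little"))
  }
  list(c(hdr, value))
}
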