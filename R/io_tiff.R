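#' Read an iViewGT-style portal TIFF
#'
#' iViewGT exports the integrated portal dose as a single-frame grayscale TIFF
#' after applying an arbitrary 16-bit scaling factor. The file carries no
#' geometry tags, so detector spacing and distances must be supplied through
#' `geometry`; reading fails hard rather than guessing, since a silently wrong
#' pixel pitch corrupts every mm-scale result.
#'
#' Raw exports are sometimes polarity-inverted (beam darker than background).
#' Polarity is detected by comparing the mean of a central 40 x 40-pixel patch
#' with the mean of a 10-pixel border frame; when the border is brighter the
#' image is flipped as `max(pixels) - pixels` and a message is emitted, so that
#' in-beam signal is always the high signal.
#'
#' @param path path to a single-frame 8- or 16-bit grayscale TIFF.
#' @param geometry named list with mandatory `pixel_spacing_detector` and `sdd`
#'   (mm), optional `sad` (default 1000 mm), `mu`, `modifier`, `beam_label`,
#'   `collimator_angle`.
#' @return a [portal_image()] with `vendor_dialect = "iview_tiff"`.
#' @export
read_iview_tiff <- function(path, geometry) {
  if (!file.exists(path)) {
    stop_format(sprintf("TIFF file not found: %s", path))
  }
  if (missing(geometry) || is.null(geometry$pixel_spacing_detector) ||
      is.null(geometry$sdd)) {
    stop_format(paste0(
      "TIFF files carry no geometry tags: `geometry` must provide ",
      "`pixel_spacing_detector` and `sdd` (mm)."
    ))
  }
  frames <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop_format(sprintf("unreadable TIFF '%s': %s", path, conditionMessage(e)))
  )
  if (length(frames) != 1) {
    stop_format(sprintf("expected a single-frame TIFF, found %d frames.", length(frames)))
  }
  px <- frames[[1]]
  if (length(dim(px)) == 3) {
    stop_format(sprintf(
      "expected a grayscale TIFF, found %d channels.", dim(px)[3]
    ))
  }
  px <- normalize_polarity(px)
  portal_image(
    pixels = px,
    pixel_spacing_detector = geometry$pixel_spacing_detector,
    sdd = geometry$sdd,
    sad = geometry$sad %||% 1000,
    mu = geometry$mu %||% NA_real_,
    modifier = geometry$modifier %||% "open",
    beam_label = geometry$beam_label %||% "6MV",
    collimator_angle = geometry$collimator_angle %||% 0,
    vendor_dialect = "iview_tiff"
  )
}

# Beam-in signal must be high. Compare a central 40x40 patch (clipped to the
# grid) against a 10-pixel border frame; invert when the border dominates.
normalize_polarity <- function(px) {
  nr <- nrow(px)
  nc <- ncol(px)
  half <- min(20L, floor(nr / 4), floor(nc / 4))
  rc <- floor(nr / 2)
  cc <- floor(nc / 2)
  central <- mean(px[(rc - half + 1):(rc + half), (cc - half + 1):(cc + half)])
  b <- min(10L, floor(nr / 4), floor(nc / 4))
  border_mask <- matrix(FALSE, nr, nc)
  border_mask[c(1:b, (nr - b + 1):nr), ] <- TRUE
  border_mask[, c(1:b, (nc - b + 1):nc)] <- TRUE
  border <- mean(px[border_mask])
  if (border > central) {
    inform("portal image polarity inverted (beam darker than background); flipped.")
    px <- max(px) - px
  }
  px
}

#' Write a portal image as an iViewGT-style TIFF
#'
#' Quantizes the signal to 16-bit grayscale (values are divided by
#' `scale_max`, 65535 by default) and writes a single-frame TIFF.
#' Round-tripping is exact for integer signals when `scale_max` is 65535;
#' continuous signals incur 16-bit quantization.
#'
#' @param image a [portal_image()].
#' @param path output path.
#' @param scale_max signal value mapped to the 16-bit maximum.
#' @return `path`, invisibly.
#' @export
write_iview_tiff <- function(image, path, scale_max = 65535) {
  stopifnot(inherits(image, "portal_image"))
  px <- image$pixels
  if (scale_max <= 0) stop_input("`scale_max` must be positive.")
  if (any(px > scale_max)) {
    stop_input("pixel values exceed `scale_max`; they would clip.")
  }
  tiff::writeTIFF(px / scale_max, path, bits.per.sample = 16L)
  invisible(path)
}
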