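#' Portal image container
#'
#' A `portal_image` holds one calibrated EPID acquisition: a rectangular grid
#' of non-negative signal values plus the geometry and acquisition metadata
#' needed to express downstream measurements in millimetres at the isocenter
#' plane.
#'
#' Coordinate conventions (fixed for the whole package):
#' * pixel indices are 0-based and a pixel's position is its centre;
#' * the image origin is the geometric centre of the grid;
#' * X is the crossline (left-right) axis and increases with column index;
#' * Y is the inline (gantry-target) axis and increases with row index, the
#'   gantry side being +Y and the target side -Y;
#' * all positions and sizes are reported in mm at the isocenter plane,
#'   i.e. detector mm scaled by `sad / sdd`.
#'
#' @param pixels numeric matrix of signal values (rows = Y, columns = X).
#' @param pixel_spacing_detector isotropic pixel pitch at the detector plane,
#'   mm/pixel.
#' @param sdd source-to-detector distance, mm.
#' @param sad source-to-axis distance, mm (1000 for all common C-arm linacs).
#' @param mu monitor units of the exposure (`NA` if unknown).
#' @param modifier `"open"` or `"wedge60"`.
#' @param beam_label free-text beam identifier, e.g. `"6MV"` or `"6FFF"`.
#' @param collimator_angle collimator angle in degrees.
#' @param acquired acquisition timestamp (`POSIXct` or `Date`), optional.
#' @param vendor_dialect `"iview_tiff"`, `"dicom_rtimage"` or `"synthetic"`.
#'
#' @return An object of class `portal_image`.
#' @seealso [pixel_spacing_isocenter()], [read_iview_tiff()],
#'   [read_dicom_rtimage()], [generate_portal_image()]
#' @export
portal_image <- function(pixels,
                         pixel_spacing_detector,
                         sdd,
                         sad = 1000,
                         mu = NA_real_,
                         modifier = c("open", "wedge60"),
                         beam_label = "6MV",
                         collimator_angle = 0,
                         acquired = NULL,
                         vendor_dialect = c("synthetic", "iview_tiff", "dicom_rtimage")) {
  modifier <- match.arg(modifier)
  vendor_dialect <- match.arg(vendor_dialect)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_input("`pixels` must be a numeric matrix.")
  }
  if (any(!is.finite(pixels))) {
    stop_input("`pixels` must be finite everywhere.")
  }
  if (any(pixels < 0)) {
    stop_input("`pixels` must be non-negative after polarity normalization.")
  }
  if (!is.numeric(pixel_spacing_detector) || length(pixel_spacing_detector) != 1 ||
      !is.finite(pixel_spacing_detector) || pixel_spacing_detector <= 0) {
    stop_input("`pixel_spacing_detector` must be a single positive number (mm/pixel).")
  }
  if (!is.finite(sdd) || !is.finite(sad) || sad <= 0 || sad > sdd) {
    stop_input("geometry requires 0 < sad <= sdd (mm).")
  }
  structure(
    list(
      pixels = pixels,
      pixel_spacing_detector = as.numeric(pixel_spacing_detector),
      sdd = as.numeric(sdd),
      sad = as.numeric(sad),
      mu = as.numeric(mu),
      modifier = modifier,
      beam_label = beam_label,
      collimator_angle = as.numeric(collimator_angle),
      acquired = acquired,
      vendor_dialect = vendor_dialect
    ),
    class = "portal_image"
  )
}

#' Pixel spacing at the isocenter plane
#'
#' Back-projects the detector pixel pitch to the isocenter plane:
#' `pixel_spacing_detector * sad / sdd`. All field sizes, centres and profile
#' positions produced by the package are expressed on this scale, so results
#' from detectors mounted at different distances are directly comparable.
#'
#' @param image a [portal_image()].
#' @return mm per pixel at the isocenter plane.
#' @examples
#' img <- generate_portal_image(beam_spec(grid = c(64, 64)))$image
#' pixel_spacing_isocenter(img)
#' @export
pixel_spacing_isocenter <- function(image) {
  stopifnot(inherits(image, "portal_image"))
  image$pixel_spacing_detector * image$sad / image$sdd
}

#' Alias used in scripted pipelines
#' @rdname pixel_spacing_isocenter
#' @export
to_isocenter_scale <- pixel_spacing_isocenter

# Pixel-centre coordinates (mm at isocenter) of all columns (axis "X") or
# rows (axis "Y") of an image. 0-based index i maps to (i - (n-1)/2) * spacing.
pixel_positions <- function(image, axis = c("X", "Y")) {
  axis <- match.arg(axis)
  n <- if (axis == "X") ncol(image$pixels) else nrow(image$pixels)
  sp <- pixel_spacing_isocenter(image)
  (seq_len(n) - 1 - (n - 1) / 2) * sp
}

#' @export
print.portal_image <- function(x, ...) {
  cat(sprintf(
    "<portal_image> %d x %d px, %.4g mm/px at isocenter (%s, %s, %s)\n",
    nrow(x$pixels), ncol(x$pixels), pixel_spacing_isocenter(x),
    x$beam_label, x$modifier, x$vendor_dialect
  ))
  cat(sprintf(
    "  SDD %.0f mm, SAD %.0f mm, MU %s, collimator %g deg\n",
    x$sdd, x$sad, ifelse(is.na(x$mu), "?", format(x$mu)), x$collimator_angle
  ))
  invisible(x)
}
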