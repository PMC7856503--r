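#' Specification of a synthetic portal beam
#'
#' Generative parameters for physically plausible flat-panel portal images of
#' flattened (FF), flattening-filter-free (FFF) and 60-degree-wedged beams.
#' Defaults emulate the canonical daily-QA acquisition: a 10 cm x 10 cm field,
#' 100 MU, imaged on a 1024 x 1024 panel with 0.4 mm detector pitch mounted at
#' 1600 mm SDD (0.25 mm per pixel at the isocenter plane).
#'
#' The noiseless signal model is separable:
#' `signal(x, y) = offset + mu * gain * Px(x) * Py(y) * M(x, y) * T(x)`,
#' with `Px`, `Py` smoothed top-hats whose logistic (sigmoid) edges sit at
#' `shift +- field/2`. `penumbra_sigma` is the Gaussian-equivalent standard
#' deviation of the edge spread; the logistic scale is
#' `penumbra_sigma * sqrt(3) / pi` (variance-matched), so a 2 mm penumbra
#' leaves the central 80 % of a 10 cm field flat to better than 0.1 %.
#' `M` is 1 for an ideal FF beam, a separable quadratic horn boost reaching
#' `horn_amplitude` at the nominal field edge for horned FF beams, and the
#' radial cone
#' `max(0, 1 - fff_falloff * r)` for FFF beams; `T` is the wedge transmission
#' `transmission * exp(-gradient * (x - shift_x))` (1 when no wedge). Noise is
#' i.i.d. Gaussian with standard deviation `noise_frac` times the local
#' noiseless signal, generated from `seed` without touching the global RNG
#' stream.
#'
#' @param field_x,field_y nominal field sizes, mm at isocenter.
#' @param penumbra_sigma logistic edge scale, mm.
#' @param beam_type `"ff"` or `"fff"`.
#' @param horn_amplitude relative off-axis horn amplitude (FF only).
#' @param fff_falloff fractional signal drop per mm off axis (FFF only).
#' @param wedge `NULL` for an open beam, or a list with `angle_deg` (60),
#'   `gradient` (fractional transmission change per mm along X) and
#'   `transmission` (bulk transmission on the axis).
#' @param mu monitor units.
#' @param gain signal per MU on the beam axis.
#' @param offset additive background signal.
#' @param noise_frac relative Gaussian noise level (0 = noiseless).
#' @param shift_x,shift_y beam-centre displacement, mm at isocenter.
#' @param grid `c(rows, cols)` detector pixels.
#' @param pixel_spacing_detector detector pitch, mm.
#' @param sdd,sad distances, mm.
#' @param beam_label free text.
#' @param seed integer RNG seed for the noise field.
#' @return a `beam_spec` list.
#' @export
beam_spec <- function(field_x = 100, field_y = 100,
                      penumbra_sigma = 2,
                      beam_type = c("ff", "fff"),
                      horn_amplitude = 0,
                      fff_falloff = 0.004,
                      wedge = NULL,
                      mu = 100, gain = 100, offset = 0,
                      noise_frac = 0,
                      shift_x = 0, shift_y = 0,
                      grid = c(1024, 1024),
                      pixel_spacing_detector = 0.4,
                      sdd = 1600, sad = 1000,
                      beam_label = NULL,
                      seed = 1L) {
  beam_type <- match.arg(beam_type)
  if (!is.null(wedge)) {
    wedge <- modifyList(list(angle_deg = 60, gradient = 0.012, transmission = 0.55), wedge)
    if (wedge$transmission <= 0) stop_input("wedge transmission must be positive.")
  }
  spec <- list(
    field_x = field_x, field_y = field_y,
    penumbra_sigma = penumbra_sigma,
    beam_type = beam_type,
    horn_amplitude = horn_amplitude,
    fff_falloff = fff_falloff,
    wedge = wedge,
    mu = mu, gain = gain, offset = offset,
    noise_frac = noise_frac,
    shift_x = shift_x, shift_y = shift_y,
    grid = as.integer(grid),
    pixel_spacing_detector = pixel_spacing_detector,
    sdd = sdd, sad = sad,
    beam_label = beam_label %||% if (beam_type == "fff") "6FFF" else "6MV",
    seed = as.integer(seed)
  )
  sp_iso <- pixel_spacing_detector * sad / sdd
  extent <- spec$grid * sp_iso
  if (field_x + abs(shift_x) * 2 >= extent[2] || field_y + abs(shift_y) * 2 >= extent[1]) {
    stop_input("field (plus shift) does not fit inside the imaged extent.")
  }
  if (gain <= 0 || mu <= 0) stop_input("`gain` and `mu` must be positive.")
  if (noise_frac < 0) stop_input("`noise_frac` must be non-negative.")
  if (penumbra_sigma <= 0) stop_input("`penumbra_sigma` must be positive.")
  structure(spec, class = "beam_spec")
}

# Noiseless signal model evaluated on arbitrary position vectors (mm at
# isocenter). Returns a length(y) x length(x) matrix.
synthetic_signal <- function(spec, x, y) {
  # logistic scale matched to a Gaussian edge-spread sd of penumbra_sigma
  s <- spec$penumbra_sigma * sqrt(3) / pi
  ex <- spec$shift_x + c(-1, 1) * spec$field_x / 2
  ey <- spec$shift_y + c(-1, 1) * spec$field_y / 2
  px <- plogis((x - ex[1]) / s) * plogis((ex[2] - x) / s)
  py <- plogis((y - ey[1]) / s) * plogis((ey[2] - y) / s)
  base <- outer(py, px) # rows = y, cols = x

  if (spec$beam_type == "fff") {
    r <- sqrt(outer((y - spec$shift_y)^2, (x - spec$shift_x)^2, `+`))
    base <- base * pmax(0, 1 - spec$fff_falloff * r)
  } else if (spec$horn_amplitude != 0) {
    hx <- 1 + spec$horn_amplitude * ((x - spec$shift_x) / (spec$field_x / 2))^2
    hy <- 1 + spec$horn_amplitude * ((y - spec$shift_y) / (spec$field_y / 2))^2
    base <- base * outer(hy, hx)
  }
  if (!is.null(spec$wedge)) {
    tx <- spec$wedge$transmission * exp(-spec$wedge$gradient * (x - spec$shift_x))
    base <- sweep(base, 2, tx, `*`)
  }
  spec$offset + spec$mu * spec$gain * base
}

#' Generate a synthetic portal image with ground truth
#'
#' Renders the [beam_spec()] signal model on the detector grid, adds seeded
#' Gaussian noise, and returns both the [portal_image()] and a ground-truth
#' record: the true edge positions, field sizes and centre, the expected
#' central-ROI mean `mu_expected` (noiseless model averaged over the 10 mm
#' ROI at the true centre) and, for wedged specs, the true wedge factor
#' `w_expected` over the same ROI. The output is bit-identical for a fixed
#' seed.
#'
#' @param spec a [beam_spec()].
#' @param roi_side ROI used for the ground-truth expectations, mm.
#' @return list with elements `image` and `truth`.
#' @export
generate_portal_image <- function(spec, roi_side = 10) {
  stopifnot(inherits(spec, "beam_spec"))
  nr <- spec$grid[1]
  nc <- spec$grid[2]
  sp_iso <- spec$pixel_spacing_detector * spec$sad / spec$sdd
  x <- (seq_len(nc) - 1 - (nc - 1) / 2) * sp_iso
  y <- (seq_len(nr) - 1 - (nr - 1) / 2) * sp_iso
  signal <- synthetic_signal(spec, x, y)
  if (spec$noise_frac > 0) {
    noise <- withr::with_seed(spec$seed, {
      matrix(rnorm(nr * nc, sd = 1), nr, nc)
    })
    signal <- signal + noise * spec$noise_frac * signal
    signal[signal < 0] <- 0
  }
  img <- portal_image(
    pixels = signal,
    pixel_spacing_detector = spec$pixel_spacing_detector,
    sdd = spec$sdd, sad = spec$sad,
    mu = spec$mu,
    modifier = if (is.null(spec$wedge)) "open" else "wedge60",
    beam_label = spec$beam_label,
    vendor_dialect = "synthetic"
  )

  half <- roi_side / 2 + 1e-9
  cols <- which(abs(x - spec$shift_x) <= half)
  rows <- which(abs(y - spec$shift_y) <= half)
  roi_model <- synthetic_signal(spec, x[cols], y[rows])
  mu_expected <- mean(roi_model)
  w_expected <- NA_real_
  if (!is.null(spec$wedge)) {
    open_spec <- spec
    open_spec$wedge <- NULL
    w_expected <- mu_expected / mean(synthetic_signal(open_spec, x[cols], y[rows]))
  }
  truth <- list(
    edge_left = spec$shift_x - spec$field_x / 2,
    edge_right = spec$shift_x + spec$field_x / 2,
    edge_target = spec$shift_y - spec$field_y / 2,
    edge_gantry = spec$shift_y + spec$field_y / 2,
    size_x = spec$field_x, size_y = spec$field_y,
    center_x = spec$shift_x, center_y = spec$shift_y,
    mu_expected = mu_expected,
    w_expected = w_expected,
    pixel_spacing_isocenter = sp_iso
  )
  list(image = img, truth = truth)
}

#' Generate an MU-linearity exposure ladder
#'
#' One image per requested MU with everything else held fixed. The two
#' conventional ladders are the 27-exposure series
#' 1-10 (step 1), 20, 40, 80, 95-105 (step 1), 150, 200, 300 MU and the
#' 8-exposure series 10, 20, 50, 80, 100, 200, 300, 600 MU; both are provided
#' as [mu_ladder_27()] / [mu_ladder_8()]. Per-image seeds are derived from
#' `seed` so replicates are independent but reproducible.
#'
#' @param mu_values MU ladder.
#' @param spec template [beam_spec()]; its `mu` and `seed` are overridden.
#' @param noise_frac noise level applied to every image.
#' @param seed base seed.
#' @return list of `list(image, truth)` pairs, one per MU.
#' @export
generate_linearity_series <- function(mu_values = mu_ladder_27(),
                                      spec = beam_spec(),
                                      noise_frac = spec$noise_frac,
                                      seed = spec$seed) {
  if (!length(mu_values)) stop_input("`mu_values` must be non-empty.")
  purrr::imap(as.numeric(mu_values), function(mu, i) {
    s <- spec
    s$mu <- mu
    s$noise_frac <- noise_frac
    s$seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    generate_portal_image(s)
  })
}

#' @rdname generate_linearity_series
#' @export
mu_ladder_27 <- function() c(1:10, 20, 40, 80, 95:105, 150, 200, 300)

#' @rdname generate_linearity_series
#' @export
mu_ladder_8 <- function() c(10, 20, 50, 80, 100, 200, 300, 600)

#' Generate an adjacent-field-size validation series
#'
#' Square fields stepping through `sizes` (conventionally 94 to 106 mm in
#' 2 mm steps) with a common centre and otherwise identical parameters; used
#' to verify that the edge detector resolves 2 mm collimator steps.
#'
#' @param sizes field sizes, mm.
#' @param spec template [beam_spec()].
#' @return list of `list(image, truth)` pairs, one per size.
#' @export
generate_field_size_series <- function(sizes = seq(94, 106, by = 2),
                                       spec = beam_spec()) {
  if (!length(sizes)) stop_input("`sizes` must be non-empty.")
  purrr::imap(as.numeric(sizes), function(sz, i) {
    s <- spec
    s$field_x <- sz
    s$field_y <- sz
    s$seed <- (spec$seed + 104729L * i) %% .Machine$integer.max
    generate_portal_image(s)
  })
}

#' Write a synthetic image plus ground-truth sidecar to disk
#'
#' Renders the spec and writes either an iViewGT-style TIFF or a DICOM RT
#' Image, with the ground-truth record as a JSON sidecar (`<path>.truth.json`)
#' for downstream validation.
#'
#' @param spec a [beam_spec()].
#' @param path output image path.
#' @param format `"tiff"` or `"dicom"`.
#' @return `path`, invisibly.
#' @export
write_synthetic_fixture <- function(spec, path, format = c("tiff", "dicom")) {
  format <- match.arg(format)
  gen <- generate_portal_image(spec)
  img <- gen$image
  if (format == "tiff") {
    img$pixels <- round(img$pixels)
    write_iview_tiff(img, path)
  } else {
    img$pixels <- round(img$pixels)
    write_dicom_rtimage(img, path)
  }
  jsonlite::write_json(gen$truth, paste0(path, ".truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
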