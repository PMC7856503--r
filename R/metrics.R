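#' Mean signal in a square central region of interest
#'
#' Averages the pixels whose centres fall inside a `roi_side` x `roi_side` mm
#' square (at the isocenter plane) centred on `center`. On a 0.25 mm grid the
#' default 10 mm ROI covers exactly 40 x 40 pixels. This mean, written
#' \eqn{\mu}, is the package's output-constancy statistic.
#'
#' @param image a [portal_image()].
#' @param center `c(x, y)` mm at isocenter; defaults to the image origin.
#' @param roi_side ROI edge length, mm at isocenter.
#' @return the arithmetic mean signal in the ROI.
#' @export
mean_central_roi <- function(image, center = c(0, 0), roi_side = 10) {
  stopifnot(inherits(image, "portal_image"))
  if (roi_side <= 0) stop_input("`roi_side` must be positive.")
  xs <- pixel_positions(image, "X")
  ys <- pixel_positions(image, "Y")
  half <- roi_side / 2 + 1e-9
  sp <- pixel_spacing_isocenter(image)
  if (center[1] - half < xs[1] - sp / 2 || center[1] + half > xs[length(xs)] + sp / 2 ||
      center[2] - half < ys[1] - sp / 2 || center[2] + half > ys[length(ys)] + sp / 2) {
    stop_geometry("the ROI extends beyond the imaged area.")
  }
  cols <- which(abs(xs - center[1]) <= half)
  rows <- which(abs(ys - center[2]) <= half)
  if (!length(cols) || !length(rows)) stop_geometry("the ROI contains no pixel centres.")
  mean(image$pixels[rows, cols])
}

#' Wedge factor
#'
#' Ratio of wedged-field to open-field central signal, `W = mu_wedge /
#' mu_open`. Because a wedge hardens the beam, W drifts when the beam energy
#' drifts, which makes it a daily beam-quality surrogate that needs no water
#' tank. Any constant detector gain cancels in the ratio.
#'
#' @param mu_wedge,mu_open central-ROI means of the wedged and open images.
#' @return the wedge factor (dimensionless).
#' @export
wedge_factor <- function(mu_wedge, mu_open) {
  if (!is.finite(mu_wedge) || !is.finite(mu_open) || mu_wedge <= 0 || mu_open <= 0) {
    stop_numeric("wedge factor needs positive mu_wedge and mu_open.")
  }
  mu_wedge / mu_open
}

#' Depth-dose beam-quality ratio
#'
#' Reference utility for cross-checking against water-tank measurements:
#' `BQ = D20 / D10`, the ratio of doses at 20 cm and 10 cm depth on the beam
#' axis. The two doses are user-supplied; no depth-dose modelling is done.
#'
#' @param d20,d10 doses at 20 cm and 10 cm depth (any common unit).
#' @return d20 / d10.
#' @export
depth_dose_bq <- function(d20, d10) {
  if (!is.finite(d20) || !is.finite(d10) || d20 <= 0 || d10 <= 0) {
    stop_numeric("depth-dose beam quality needs positive d20 and d10.")
  }
  d20 / d10
}

#' Daily metric set from one open (+ optional wedge) acquisition
#'
#' Runs the full analysis chain on the open image — field geometry, central-80%
#' profiles, flatness (suppressed for FFF beams, which have no flat region),
#' symmetry, central-ROI mean — and, when a wedge image is supplied, the wedge
#' factor. Both ROIs are placed at the open field's detected centre: the two
#' images come from the same session, and displacing the ROIs identically is
#' what makes W robust to small setup errors. A wedge field whose size
#' disagrees with the open field by more than `size_consistency_mm` indicates
#' a mixed-up acquisition and raises an error.
#'
#' @param open_image open-field [portal_image()].
#' @param wedge_image optional 60-degree-wedge [portal_image()].
#' @param is_fff flattening-filter-free beam? Suppresses flatness.
#' @param roi_side central-ROI edge, mm.
#' @param n_lines profile averaging band.
#' @param size_consistency_mm maximum tolerated open/wedge size disagreement.
#' @return a `field_metrics` object; see [as_tibble.field_metrics()].
#' @export
analyze_acquisition <- function(open_image, wedge_image = NULL, is_fff = FALSE,
                                roi_side = 10, n_lines = 10,
                                size_consistency_mm = 5) {
  stopifnot(inherits(open_image, "portal_image"))
  geom <- field_geometry(open_image, n_lines = n_lines)
  center <- c(geom$center_x, geom$center_y)

  px_region <- in_field_region(
    extract_profile(open_image, "X", geom$center_px_y, n_lines), geom
  )
  py_region <- in_field_region(
    extract_profile(open_image, "Y", geom$center_px_x, n_lines), geom
  )
  mu_open <- mean_central_roi(open_image, center, roi_side)

  mu_wedge <- NA_real_
  wf <- NA_real_
  if (!is.null(wedge_image)) {
    stopifnot(inherits(wedge_image, "portal_image"))
    wgeom <- field_geometry(wedge_image, n_lines = n_lines)
    if (abs(wgeom$size_x - geom$size_x) > size_consistency_mm ||
        abs(wgeom$size_y - geom$size_y) > size_consistency_mm) {
      stop_input(sprintf(
        "wedge field size (%.1f x %.1f mm) disagrees with the open field (%.1f x %.1f mm) by more than %g mm.",
        wgeom$size_x, wgeom$size_y, geom$size_x, geom$size_y, size_consistency_mm
      ))
    }
    mu_wedge <- mean_central_roi(wedge_image, center, roi_side)
    wf <- wedge_factor(mu_wedge, mu_open)
  }

  structure(
    list(
      mu_open = mu_open,
      mu_wedge = mu_wedge,
      flatness_x = if (is_fff) NA_real_ else flatness(px_region, geom$center_x),
      flatness_y = if (is_fff) NA_real_ else flatness(py_region, geom$center_y),
      symmetry_x = symmetry(px_region, geom$center_x),
      symmetry_y = symmetry(py_region, geom$center_y),
      size_x = geom$size_x,
      size_y = geom$size_y,
      center_x = geom$center_x,
      center_y = geom$center_y,
      wedge_factor = wf,
      is_fff = is_fff,
      beam_label = open_image$beam_label,
      acquired = open_image$acquired
    ),
    class = "field_metrics"
  )
}

#' @export
print.field_metrics <- function(x, ...) {
  cat(sprintf("<field_metrics> beam %s%s\n", x$beam_label, if (x$is_fff) " (FFF)" else ""))
  cat(sprintf("  mu_open %.4g", x$mu_open))
  if (!is.na(x$wedge_factor)) cat(sprintf(", W %.4f", x$wedge_factor))
  cat("\n")
  if (!x$is_fff) {
    cat(sprintf("  flatness  X %.3f %%  Y %.3f %%\n", x$flatness_x, x$flatness_y))
  }
  cat(sprintf("  symmetry  X %.3f %%  Y %.3f %%\n", x$symmetry_x, x$symmetry_y))
  cat(sprintf(
    "  size %.2f x %.2f mm, centre (%.3f, %.3f) mm\n",
    x$size_x, x$size_y, x$center_x, x$center_y
  ))
  invisible(x)
}

#' One-row tibble view of a metric set
#' @param x a `field_metrics` object.
#' @param ... unused.
#' @export
as_tibble.field_metrics <- function(x, ...) {
  tibble::as_tibble(x[c(
    "beam_label", "is_fff", "mu_open", "mu_wedge", "wedge_factor",
    "flatness_x", "flatness_y", "symmetry_x", "symmetry_y",
    "size_x", "size_y", "center_x", "center_y"
  )])
}

#' ROI shift-sensitivity scan
#'
#' Quantifies how a misplaced readout position biases the output and
#' beam-quality statistics: for each cardinal direction and offset the ROI is
#' displaced from the detected field centre and the relative change of mu
#' (and of W, when a wedge image is present) is recorded as
#' `(shifted - reference) / reference * 100`. Both wedge and open ROIs are
#' displaced by the same vector, emulating a setup error of the whole imager.
#' Offsets whose ROI leaves the imaged area are flagged rather than fatal.
#'
#' @param open_image,wedge_image portal images from one session (wedge
#'   optional).
#' @param offsets displacement magnitudes in mm; the conventional scan is
#'   1-10 mm in 1 mm steps plus 15, 20 and 30 mm.
#' @param directions subset of `c("left", "right", "gantry", "target")`.
#' @param roi_side ROI edge, mm.
#' @return tibble with columns `direction`, `offset_mm`, `output_dev_pct`,
#'   `bq_dev_pct`, `flagged`.
#' @export
shift_sensitivity <- function(open_image, wedge_image = NULL,
                              offsets = c(1:10, 15, 20, 30),
                              directions = c("left", "right", "gantry", "target"),
                              roi_side = 10) {
  directions <- match.arg(directions, several.ok = TRUE)
  if (!length(offsets) || any(offsets < 0)) {
    stop_input("`offsets` must be non-negative displacement magnitudes in mm.")
  }
  geom <- field_geometry(open_image)
  center <- c(geom$center_x, geom$center_y)
  mu0 <- mean_central_roi(open_image, center, roi_side)
  w0 <- NA_real_
  if (!is.null(wedge_image)) {
    w0 <- wedge_factor(mean_central_roi(wedge_image, center, roi_side), mu0)
  }
  unit <- list(
    left = c(-1, 0), right = c(1, 0),
    gantry = c(0, 1), target = c(0, -1)
  )
  grid <- tidyr_expand(directions, offsets)
  rows <- purrr::pmap(grid, function(direction, offset_mm) {
    shifted <- center + unit[[direction]] * offset_mm
    res <- tryCatch(
      {
        mu_s <- mean_central_roi(open_image, shifted, roi_side)
        out_dev <- (mu_s - mu0) / mu0 * 100
        bq_dev <- NA_real_
        if (!is.null(wedge_image)) {
          w_s <- wedge_factor(mean_central_roi(wedge_image, shifted, roi_side), mu_s)
          bq_dev <- (w_s - w0) / w0 * 100
        }
        list(output_dev_pct = out_dev, bq_dev_pct = bq_dev, flagged = FALSE)
      },
      epidqa_geometry_error = function(e) {
        list(output_dev_pct = NA_real_, bq_dev_pct = NA_real_, flagged = TRUE)
      }
    )
    tibble::tibble(
      direction = direction, offset_mm = offset_mm,
      output_dev_pct = res$output_dev_pct, bq_dev_pct = res$bq_dev_pct,
      flagged = res$flagged
    )
  })
  dplyr::bind_rows(rows)
}

# direction x offset grid in scan order (directions outer, offsets inner).
tidyr_expand <- function(directions, offsets) {
  tibble::tibble(
    direction = rep(directions, each = length(offsets)),
    offset_mm = rep(as.numeric(offsets), times = length(directions))
  )
}

#' Radiation centre from a collimator-opposed image pair
#'
#' Collimator asymmetries displace the apparent field centre in opposite
#' directions at collimator 90 and 270 degrees, so the mean of the two
#' detected centres is the collimator-independent beam (radiation) centre.
#'
#' @param image_c90,image_c270 portal images of the same field acquired at
#'   collimator angles 90 and 270 degrees.
#' @return named numeric `c(x, y)` mm at isocenter.
#' @export
collimator_pair_center <- function(image_c90, image_c270) {
  g1 <- field_geometry(image_c90)
  g2 <- field_geometry(image_c270)
  c(
    x = (g1$center_x + g2$center_x) / 2,
    y = (g1$center_y + g2$center_y) / 2
  )
}

#' Dose-response linearity fit
#'
#' Ordinary least squares of the central-ROI mean against delivered monitor
#' units, `mu = slope * MU + intercept`. The coefficient of determination
#' `r_squared = 1 - SS_res / SS_tot` is the figure of merit for detector
#' linearity; an ideal integrating imager gives 1 across the whole MU ladder.
#'
#' @param series data frame with columns `mu_set` (delivered MU) and
#'   `mu_measured` (central-ROI mean), one row per exposure; at least 3
#'   distinct MU values.
#' @return an object of class `linearity_fit` with [tidy()] and [glance()]
#'   methods; elements `slope`, `intercept`, `r_squared`, `n`, `model`.
#' @export
linearity_fit <- function(series) {
  series <- tibble::as_tibble(series)
  if (!all(c("mu_set", "mu_measured") %in% names(series))) {
    stop_input("`series` needs columns `mu_set` and `mu_measured`.")
  }
  if (nrow(series) < 3 || length(unique(series$mu_set)) < 3) {
    stop_input("linearity needs at least 3 distinct MU values.")
  }
  if (stats::var(series$mu_set) == 0) stop_input("MU values have zero variance.")
  fit <- lm(mu_measured ~ mu_set, data = series)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((series$mu_measured - mean(series$mu_measured))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = max(0, min(1, r2)),
      n = nrow(series),
      series = series,
      model = fit
    ),
    class = "linearity_fit"
  )
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf(
    "<linearity_fit> mu = %.6g * MU + %.6g, R^2 = %.6f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}

#' @rdname linearity_fit
#' @param x a `linearity_fit`.
#' @param ... unused.
#' @export
tidy.linearity_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    # a perfect fit makes summary() warn about unreliable inference; the
    # standard errors (zero) are still what we want to report
    std.error = suppressWarnings(summary(x$model)$coefficients[, "Std. Error"])
  )
}

#' @rdname linearity_fit
#' @export
glance.linearity_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    r.squared = x$r_squared, nobs = x$n
  )
}

#' Long-term summary of repeated measurements
#'
#' Sample mean and (n-1) standard deviation per component of a sequence of
#' daily records: either a data frame of centre coordinates (or any numeric
#' columns) or a plain numeric vector of output ratios.
#'
#' @param records data frame with numeric columns, or a numeric vector.
#' @return tibble with columns `component`, `mean`, `sd`, `n`.
#' @export
long_term_summary <- function(records) {
  if (is.numeric(records) && is.null(dim(records))) {
    records <- tibble::tibble(value = records)
  }
  records <- tibble::as_tibble(records)
  records <- records[vapply(records, is.numeric, logical(1))]
  if (nrow(records) < 2) stop_input("long-term summary needs at least 2 records.")
  if (!ncol(records)) stop_input("no numeric components to summarize.")
  purrr::map_dfr(names(records), function(nm) {
    v <- records[[nm]]
    tibble::tibble(component = nm, mean = mean(v), sd = sd(v), n = length(v))
  })
}

#' Export a sensitivity scan or linearity series as CSV
#'
#' @param x a tibble from [shift_sensitivity()], a `linearity_fit`, or any
#'   data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  if (inherits(x, "linearity_fit")) {
    df <- x$series
    df$fit_slope <- x$slope
    df$fit_intercept <- x$intercept
    df$fit_r_squared <- x$r_squared
    x <- df
  }
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
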