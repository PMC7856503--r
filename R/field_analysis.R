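#' Beam profile container
#'
#' A 1-D signal versus position (mm at the isocenter plane) along the
#' crossline (X) or inline (Y) axis. Positions are strictly increasing with
#' uniform step; at least 16 samples are required so that derivative-based
#' edge detection is meaningful.
#'
#' @param axis `"X"` or `"Y"`.
#' @param positions mm at isocenter, uniform step.
#' @param values non-negative finite signal, same length as `positions`.
#' @return object of class `beam_profile` (also a tibble-convertible list).
#' @export
beam_profile <- function(axis = c("X", "Y"), positions, values) {
  axis <- match.arg(axis)
  n <- length(positions)
  if (n < 16 || length(values) != n) {
    stop_input("a beam profile needs >= 16 samples and equal-length positions/values.")
  }
  steps <- diff(positions)
  if (any(steps <= 0) || diff(range(steps)) > 1e-9) {
    stop_input("profile positions must be strictly increasing with uniform step.")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_input("profile values must be finite and non-negative.")
  }
  structure(
    list(axis = axis, positions = as.numeric(positions), values = as.numeric(values)),
    class = "beam_profile"
  )
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf(
    "<beam_profile> %s axis, %d samples, %.4g mm step, span [%.4g, %.4g] mm\n",
    x$axis, length(x$positions), x$positions[2] - x$positions[1],
    min(x$positions), max(x$positions)
  ))
  invisible(x)
}

#' @export
as.data.frame.beam_profile <- function(x, ...) {
  data.frame(axis = x$axis, position_mm = x$positions, value = x$values)
}

profile_step <- function(profile) profile$positions[2] - profile$positions[1]

#' Extract an averaged crossline or inline profile
#'
#' Averages a band of `n_lines` adjacent rows (axis `"X"`) or columns (axis
#' `"Y"`) centred on `center_row_or_col` and returns the mean signal versus
#' position in mm at the isocenter plane, origin at the image centre.
#' Ten lines (about 2.5 mm on a 0.25 mm grid) is the conventional band width:
#' wide enough to suppress single-pixel noise, narrow enough not to blur the
#' penumbra of a tilted field.
#'
#' @param image a [portal_image()].
#' @param axis `"X"` (values vs column position, rows averaged) or `"Y"`.
#' @param center_row_or_col 0-based, possibly fractional pixel index of the
#'   band centre. Defaults to the grid centre.
#' @param n_lines number of lines averaged.
#' @return a [beam_profile()].
#' @export
extract_profile <- function(image, axis = c("X", "Y"),
                            center_row_or_col = NULL, n_lines = 10) {
  stopifnot(inherits(image, "portal_image"))
  axis <- match.arg(axis)
  px <- image$pixels
  n_across <- if (axis == "X") nrow(px) else ncol(px)
  if (is.null(center_row_or_col)) center_row_or_col <- (n_across - 1) / 2
  start <- round(center_row_or_col - (n_lines - 1) / 2)
  idx0 <- start + seq_len(n_lines) - 1 # 0-based line indices
  if (n_lines < 1 || any(idx0 < 0) || any(idx0 >= n_across)) {
    stop_geometry(sprintf(
      "averaging band [%d, %d] exceeds the %d-line grid along %s.",
      min(idx0), max(idx0), n_across, if (axis == "X") "Y" else "X"
    ))
  }
  vals <- if (axis == "X") {
    colMeans(px[idx0 + 1, , drop = FALSE])
  } else {
    rowMeans(px[, idx0 + 1, drop = FALSE])
  }
  beam_profile(axis, pixel_positions(image, axis), vals)
}

# Gaussian smoothing with edge replication; sigma in samples.
gaussian_smooth <- function(v, sigma = 1) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  padded <- c(rep(v[1], r), v, rep(v[length(v)], r))
  stats::filter(padded, k, sides = 2)[(r + 1):(r + length(v))]
}

#' Locate the two field edges of a profile
#'
#' The field edge is the penumbral inflection point: the position where the
#' first derivative of the profile is extremal (equivalently, where its second
#' derivative crosses zero). The profile is Gaussian-smoothed (`smooth_sigma`
#' samples), differentiated by central differences, and each derivative
#' extremum is refined to sub-pixel precision with a three-point parabola.
#'
#' @param profile a [beam_profile()] containing one in-field plateau or peak
#'   flanked by two penumbrae.
#' @param smooth_sigma smoothing scale in samples.
#' @return named numeric `c(edge_low, edge_high)` in mm at isocenter.
#' @export
detect_field_edges <- function(profile, smooth_sigma = 1) {
  stopifnot(inherits(profile, "beam_profile"))
  v <- gaussian_smooth(profile$values, smooth_sigma)
  n <- length(v)
  h <- profile_step(profile)
  d <- (v[3:n] - v[1:(n - 2)]) / (2 * h) # derivative at samples 2..n-1
  dpos <- profile$positions[2:(n - 1)]
  m <- length(d)

  pick <- function(side) {
    cand <- if (side == "low") which(d == max(d)) else which(d == min(d))
    if (length(cand) > 1) {
      # Adjacent ties happen whenever an edge falls midway between two
      # samples; the parabolic refinement resolves them exactly, so they are
      # not worth logging. Non-adjacent ties are a genuine degeneracy: take
      # the candidate nearest the profile midline and say so.
      if (any(diff(cand) > 1)) {
        inform(sprintf("tied derivative extrema on the %s side; nearest centre taken.", side))
      }
      mid <- (dpos[1] + dpos[m]) / 2
      cand <- cand[which.min(abs(dpos[cand] - mid))]
    }
    cand
  }
  k_lo <- pick("low")
  k_hi <- pick("high")
  if (d[k_lo] <= 0) {
    stop_detection("no rising penumbra found on the low side of the profile.")
  }
  if (d[k_hi] >= 0) {
    stop_detection("no falling penumbra found on the high side of the profile.")
  }
  if (k_lo == 1 || k_lo == m || k_hi == 1 || k_hi == m) {
    side <- if (k_lo %in% c(1, m)) "low" else "high"
    stop_detection(sprintf("derivative extremum on the %s side sits at the profile boundary.", side))
  }
  if (k_lo >= k_hi) {
    stop_detection("rising edge found at or beyond the falling edge; no plateau between penumbrae.")
  }
  refine <- function(k) {
    a <- d[k - 1]; b <- d[k]; cc <- d[k + 1]
    den <- a - 2 * b + cc
    delta <- if (abs(den) < .Machine$double.eps * max(abs(c(a, b, cc, 1)))) 0 else 0.5 * (a - cc) / den
    dpos[k] + max(-1, min(1, delta)) * h
  }
  c(edge_low = refine(k_lo), edge_high = refine(k_hi))
}

#' Field geometry: edges, sizes and centre of a portal image
#'
#' Two-pass procedure. Pass 1 pulls X and Y profiles through the grid centre,
#' detects the four edges and takes edge midpoints as a provisional centre;
#' pass 2 re-extracts both profiles through that centre and re-detects. The
#' centre of a rectangular field from edge midpoints coincides with the
#' intersection of the field diagonals. If the centre moves by more than
#' `max_shift_px` pixels between passes a warning is raised and the pass-2
#' result returned.
#'
#' @param image a [portal_image()] with one rectangular (or FFF-peaked) field
#'   well inside the imaged area.
#' @param n_lines averaging band passed to [extract_profile()].
#' @param max_shift_px convergence tolerance between passes, pixels.
#' @return a `field_geometry` list: `edge_left`, `edge_right` (X, mm),
#'   `edge_target`, `edge_gantry` (Y, mm; gantry side is +Y so
#'   `edge_gantry > edge_target`), `size_x`, `size_y`, `center_x`, `center_y`
#'   (mm at isocenter) and `center_px_x`, `center_px_y` (fractional 0-based
#'   pixels).
#' @export
field_geometry <- function(image, n_lines = 10, max_shift_px = 2) {
  stopifnot(inherits(image, "portal_image"))
  sp <- pixel_spacing_isocenter(image)
  nr <- nrow(image$pixels)
  nc <- ncol(image$pixels)
  mm_to_col <- function(x) x / sp + (nc - 1) / 2
  mm_to_row <- function(y) y / sp + (nr - 1) / 2

  one_pass <- function(center_row, center_col) {
    ex <- detect_field_edges(extract_profile(image, "X", center_row, n_lines))
    ey <- detect_field_edges(extract_profile(image, "Y", center_col, n_lines))
    list(x = ex, y = ey,
         cx = mean(ex), cy = mean(ey))
  }

  p1 <- one_pass((nr - 1) / 2, (nc - 1) / 2)
  p2 <- one_pass(mm_to_row(p1$cy), mm_to_col(p1$cx))
  shift_px <- max(abs(p2$cx - p1$cx), abs(p2$cy - p1$cy)) / sp
  if (shift_px > max_shift_px) {
    warn(sprintf(
      "field centre moved %.2f px between passes (> %g px); result from pass 2.",
      shift_px, max_shift_px
    ))
  }
  structure(
    list(
      edge_left = unname(p2$x["edge_low"]),
      edge_right = unname(p2$x["edge_high"]),
      edge_target = unname(p2$y["edge_low"]),
      edge_gantry = unname(p2$y["edge_high"]),
      size_x = unname(diff(p2$x)),
      size_y = unname(diff(p2$y)),
      center_x = p2$cx,
      center_y = p2$cy,
      center_px_x = mm_to_col(p2$cx),
      center_px_y = mm_to_row(p2$cy)
    ),
    class = "field_geometry"
  )
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf(
    "<field_geometry> size %.2f x %.2f mm, centre (%.2f, %.2f) mm at isocenter\n",
    x$size_x, x$size_y, x$center_x, x$center_y
  ))
  invisible(x)
}

#' Restrict a profile to the central fraction of the field
#'
#' Keeps the samples whose positions lie within `fraction` of the field size,
#' centred on the field centre of the profile's axis. Flatness and symmetry
#' are evaluated on this central 80 % region by convention, so that the
#' penumbrae do not dominate either statistic.
#'
#' @param profile a [beam_profile()].
#' @param geometry a [field_geometry()] for the same image.
#' @param fraction kept fraction of the field size.
#' @return a [beam_profile()] restricted to the in-field region.
#' @export
in_field_region <- function(profile, geometry, fraction = 0.8) {
  stopifnot(inherits(profile, "beam_profile"), inherits(geometry, "field_geometry"))
  if (fraction <= 0) stop_input("`fraction` must be positive.")
  if (profile$axis == "X") {
    ctr <- geometry$center_x
    size <- geometry$size_x
  } else {
    ctr <- geometry$center_y
    size <- geometry$size_y
  }
  half <- fraction * size / 2
  keep <- profile$positions >= ctr - half & profile$positions <= ctr + half
  if (!any(keep)) {
    stop_geometry("the in-field region contains no profile samples.")
  }
  beam_profile(profile$axis, profile$positions[keep], profile$values[keep])
}

# Linear interpolation of the profile at the field-centre position; the
# denominator of flatness and symmetry.
profile_center_value <- function(profile, center) {
  dc <- approx(profile$positions, profile$values, xout = center, rule = 1)$y
  if (is.na(dc)) stop_geometry("field centre lies outside the profile span.")
  dc
}

#' Beam flatness
#'
#' `(Dmax - Dmin) / Dcenter * 100` over the supplied in-field region, where
#' `Dcenter` is the profile value linearly interpolated at the field-centre
#' position (a definition that stays meaningful for peaked FFF profiles,
#' although flatness is conventionally not reported for them).
#'
#' @param region the central-80 % [beam_profile()] from [in_field_region()].
#' @param center field-centre position for this axis, mm; defaults to the
#'   midpoint of the region span.
#' @return flatness in percent (non-negative).
#' @export
flatness <- function(region, center = NULL) {
  stopifnot(inherits(region, "beam_profile"))
  center <- center %||% mean(range(region$positions))
  dc <- profile_center_value(region, center)
  if (dc <= 0) stop_numeric("central dose must be positive to normalize flatness.")
  (max(region$values) - min(region$values)) / dc * 100
}

#' Beam symmetry
#'
#' `max |D(p) - D(2c - p)| / Dcenter * 100`: the largest imbalance between
#' points mirrored about the field central axis `c`, over all samples of the
#' in-field region whose mirror image also falls inside it. Mirrored values
#' are obtained by linear interpolation.
#'
#' @inheritParams flatness
#' @return symmetry in percent (non-negative).
#' @export
symmetry <- function(region, center = NULL) {
  stopifnot(inherits(region, "beam_profile"))
  center <- center %||% mean(range(region$positions))
  dc <- profile_center_value(region, center)
  if (dc <= 0) stop_numeric("central dose must be positive to normalize symmetry.")
  mirrored <- 2 * center - region$positions
  ok <- mirrored >= region$positions[1] & mirrored <= region$positions[length(region$positions)]
  if (!any(ok)) stop_geometry("no mirror pairs fall inside the region.")
  dm <- approx(region$positions, region$values, xout = mirrored[ok], rule = 1)$y
  max(abs(region$values[ok] - dm)) / dc * 100
}
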