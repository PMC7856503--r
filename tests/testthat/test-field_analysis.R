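test_that("extract_profile averages the requested band", {
  img <- constant_image(7, n = 64)
  p <- extract_profile(img, "X")
  expect_true(all(p$values == 7))
  expect_length(p$values, 64)
  expect_equal(p$positions[2] - p$positions[1], 0.25)

  # row i (0-based) holds value i: a 10-row band on rows 10..19 averages 14.5
  ramp <- portal_image(matrix(0:63, 64, 64), 0.4, 1600)
  p2 <- extract_profile(ramp, "X", center_row_or_col = 14.5, n_lines = 10)
  expect_true(all(abs(p2$values - 14.5) < 1e-12))

  # a single line is returned verbatim
  p3 <- extract_profile(ramp, "X", center_row_or_col = 20, n_lines = 1)
  expect_true(all(p3$values == 20))

  # Y profiles run along rows
  p4 <- extract_profile(ramp, "Y", center_row_or_col = 31.5, n_lines = 10)
  expect_equal(p4$values, 0:63, ignore_attr = TRUE)

  expect_error(
    extract_profile(ramp, "X", center_row_or_col = 2, n_lines = 10),
    class = "epidqa_geometry_error"
  )
})

test_that("field edges are recovered to sub-pixel precision", {
  spec <- beam_spec(seed = 21) # 100 mm field, sigma 2 mm, 0.25 mm sampling
  p <- profile_of(spec)
  edges <- detect_field_edges(p)
  expect_lt(abs((edges["edge_high"] - edges["edge_low"]) - 100), HALF_PIXEL)
  expect_lt(abs(edges["edge_low"] - (-50)), HALF_PIXEL)
})

test_that("mirroring a profile swaps and negates its edges", {
  p <- profile_of(beam_spec(shift_x = 4.25, seed = 22))
  e <- detect_field_edges(p)
  em <- detect_field_edges(mirror_profile(p))
  expect_equal(unname(em["edge_low"]), -unname(e["edge_high"]), tolerance = 1e-9)
  expect_equal(unname(em["edge_high"]), -unname(e["edge_low"]), tolerance = 1e-9)
})

test_that("profiles without two opposite penumbrae are rejected", {
  n <- 64
  pos <- seq(-7.875, 7.875, by = 0.25)
  ramp <- beam_profile("X", pos, seq(1, 100, length.out = n))
  expect_error(detect_field_edges(ramp), class = "epidqa_detection_error")
  falling <- beam_profile("X", pos, seq(100, 1, length.out = n))
  expect_error(detect_field_edges(falling), class = "epidqa_detection_error")
})

test_that("in_field_region keeps the central fraction of the field", {
  img <- generate_portal_image(beam_spec(seed = 23))$image
  geom <- field_geometry(img)
  p <- extract_profile(img, "X", geom$center_px_y)

  r80 <- in_field_region(p, geom, 0.8)
  expect_lt(abs(diff(range(r80$positions)) - 80), 0.5)

  r100 <- in_field_region(p, geom, 1)
  expect_lt(abs(diff(range(r100$positions)) - geom$size_x), 0.5)

  img50 <- generate_portal_image(beam_spec(field_x = 50, field_y = 50, seed = 24))$image
  geom50 <- field_geometry(img50)
  p50 <- extract_profile(img50, "X", geom50$center_px_y)
  r50 <- in_field_region(p50, geom50, 0.8)
  expect_lt(abs(diff(range(r50$positions)) - 40), 0.5)
})

test_that("flatness matches its defining ratio and is scale invariant", {
  expect_equal(flatness(flat_region()), 0)

  vals <- rep(100, 16)
  vals[2] <- 105
  vals[15] <- 95
  expect_equal(flatness(flat_region(vals), center = 0), 10)

  scaled <- flat_region(vals * 3.7)
  expect_equal(flatness(scaled, center = 0), 10)

  zero <- beam_profile("X", seq(-7.5, 7.5, 1), rep(0, 16))
  expect_error(flatness(zero, center = 0), class = "epidqa_numeric_error")
})

test_that("symmetry maximizes the mirrored-pair imbalance", {
  expect_equal(symmetry(flat_region(), center = 0), 0)

  # D(+3.5) = 102, D(-3.5) = 98, all other pairs equal, Dcenter = 100
  pos <- seq(-7.5, 7.5, by = 1)
  vals <- rep(100, 16)
  vals[pos == 3.5] <- 102
  vals[pos == -3.5] <- 98
  region <- beam_profile("X", pos, vals)
  expect_equal(symmetry(region, center = 0), 4)

  # reflecting the region about the centre leaves S unchanged
  expect_equal(symmetry(mirror_profile(region), center = 0), 4)
})

test_that("field geometry recovers a shifted field and its centre", {
  g <- generate_portal_image(beam_spec(shift_x = 3, seed = 25))
  geom <- field_geometry(g$image)
  expect_lt(abs(geom$center_x - 3), HALF_PIXEL)
  expect_lt(abs(geom$center_y - 0), HALF_PIXEL)
  expect_lt(abs(geom$size_x - 100), 0.25)
  expect_lt(abs(geom$size_y - 100), 0.25)
  expect_gt(geom$edge_right, geom$edge_left)
  expect_gt(geom$edge_gantry, geom$edge_target)
  expect_equal(geom$size_x, geom$edge_right - geom$edge_left)

  centred <- field_geometry(generate_portal_image(beam_spec(seed = 26))$image)
  expect_lt(abs(centred$center_x), HALF_PIXEL)
  expect_lt(abs(centred$center_y), HALF_PIXEL)
})

test_that("field centre is equivariant under whole-pixel translations", {
  base <- generate_portal_image(small_spec(field_x = 60, field_y = 60, seed = 27))$image
  g0 <- field_geometry(base)
  sp <- pixel_spacing_isocenter(base)
  for (k in c(-15L, -4L, 7L, 20L)) {
    shifted <- base
    # roll columns by k pixels; wrapped-in values are far-field background
    idx <- ((seq_len(ncol(base$pixels)) - 1 - k) %% ncol(base$pixels)) + 1
    shifted$pixels <- base$pixels[, idx]
    gk <- field_geometry(shifted)
    expect_lt(abs((gk$center_x - g0$center_x) - k * sp), 1e-6)
    expect_lt(abs(gk$size_x - g0$size_x), 1e-6)
    expect_lt(abs(gk$size_y - g0$size_y), 1e-6)
  }
})

test_that("edge recovery holds across the documented size/penumbra/shift grid", {
  grid <- expand.grid(
    size = c(40, 120, 200),
    sigma = c(1, 4),
    shift = c(-10, 0, 10)
  )
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    g <- generate_portal_image(beam_spec(
      field_x = gr$size, field_y = gr$size,
      penumbra_sigma = gr$sigma,
      shift_x = gr$shift, shift_y = -gr$shift / 2,
      seed = 30 + i
    ))
    geom <- field_geometry(g$image)
    expect_lt(abs(geom$size_x - gr$size), HALF_PIXEL)
    expect_lt(abs(geom$size_y - gr$size), HALF_PIXEL)
    expect_lt(abs(geom$center_x - gr$shift), HALF_PIXEL)
    expect_lt(abs(geom$center_y - (-gr$shift / 2)), HALF_PIXEL)
  }
})

test_that("noiseless flat fields are flat and symmetric after analysis", {
  # closure grid: penumbra small enough that the 80 % boundary sits >= 6.5
  # logistic scales inside the edge
  grid <- expand.grid(size = c(80, 100, 140, 200), sigma = c(1, 2))
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    g <- generate_portal_image(beam_spec(
      field_x = gr$size, field_y = gr$size, penumbra_sigma = gr$sigma,
      seed = 50 + i
    ))
    geom <- field_geometry(g$image)
    p <- extract_profile(g$image, "X", geom$center_px_y)
    region <- in_field_region(p, geom)
    expect_lt(flatness(region, geom$center_x), 0.1)
    expect_lt(symmetry(region, geom$center_x), 0.05)
  }
})

test_that("size estimates tolerate 0.5 % image noise", {
  n_rep <- 200
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    g <- generate_portal_image(small_spec(noise_frac = 0.005, seed = 1000 + r))
    geom <- field_geometry(g$image)
    ok[r] <- abs(geom$size_x - 100) < 0.25 && abs(geom$size_y - 100) < 0.25
  }
  expect_gte(mean(ok), 0.95)
})
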