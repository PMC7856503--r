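test_that("the central ROI covers exactly 40 x 40 pixels on a 0.25 mm grid", {
  px <- matrix(0, 1024, 1024)
  px[493:532, 493:532] <- 1 # pixel centres with |x|,|y| < 5 mm
  img <- portal_image(px, 0.4, 1600)
  expect_equal(mean_central_roi(img, c(0, 0), 10), 1)
  # one pixel wider on each side dilutes the mean
  expect_lt(mean_central_roi(img, c(0, 0), 10.5), 1)

  expect_equal(mean_central_roi(constant_image(42), c(0, 0), 10), 42)
  expect_error(
    mean_central_roi(constant_image(1, n = 16), c(0, 0), 10),
    class = "epidqa_geometry_error"
  )
})

test_that("central-ROI signal scales linearly with MU", {
  g100 <- generate_portal_image(small_spec(mu = 100, seed = 31))
  g200 <- generate_portal_image(small_spec(mu = 200, seed = 31))
  m100 <- mean_central_roi(g100$image)
  m200 <- mean_central_roi(g200$image)
  expect_equal(m200 / m100, 2, tolerance = 1e-12)
})

test_that("wedge factor and depth-dose ratios follow their definitions", {
  expect_equal(wedge_factor(100, 100), 1)
  expect_equal(wedge_factor(60, 100), 0.6)
  expect_equal(wedge_factor(60 * 3, 100 * 3), 0.6)
  expect_error(wedge_factor(0, 100), class = "epidqa_numeric_error")
  expect_error(wedge_factor(10, -1), class = "epidqa_numeric_error")

  expect_equal(depth_dose_bq(30, 30), 1)
  expect_equal(depth_dose_bq(30, 60), 0.5)
  expect_equal(depth_dose_bq(300, 600), 0.5)
  expect_error(depth_dose_bq(-1, 2), class = "epidqa_numeric_error")
})

test_that("analyze_acquisition reproduces the generator's wedge factor", {
  open_spec <- beam_spec(seed = 32)
  wedge_spec <- beam_spec(wedge = list(), seed = 33)
  open_g <- generate_portal_image(open_spec)
  wedge_g <- generate_portal_image(wedge_spec)
  m <- analyze_acquisition(open_g$image, wedge_g$image)
  expect_lt(abs(m$wedge_factor / wedge_g$truth$w_expected - 1) * 100, 0.2)
  expect_false(is.na(m$flatness_x))
  expect_equal(m$mu_open, open_g$truth$mu_expected, tolerance = 1e-3)
})

test_that("FFF acquisitions carry no flatness; open-only sessions carry no W", {
  fff <- generate_portal_image(beam_spec(beam_type = "fff", seed = 34))$image
  m <- analyze_acquisition(fff, is_fff = TRUE)
  expect_true(is.na(m$flatness_x) && is.na(m$flatness_y))
  expect_false(is.na(m$symmetry_x))

  open_only <- analyze_acquisition(generate_portal_image(beam_spec(seed = 35))$image)
  expect_true(is.na(open_only$wedge_factor))
  tbl <- tibble::as_tibble(open_only)
  expect_identical(nrow(tbl), 1L)
})

test_that("a wedge image with a different field size is rejected", {
  open_img <- generate_portal_image(beam_spec(seed = 36))$image
  wedge_img <- generate_portal_image(
    beam_spec(field_x = 90, field_y = 90, wedge = list(), seed = 37)
  )$image
  expect_error(
    analyze_acquisition(open_img, wedge_img),
    class = "epidqa_input_error"
  )
})

test_that("the wedge factor is invariant to a global detector gain", {
  open_img <- generate_portal_image(beam_spec(seed = 38))$image
  wedge_img <- generate_portal_image(beam_spec(wedge = list(), seed = 39))$image
  m1 <- analyze_acquisition(open_img, wedge_img)
  open_img$pixels <- open_img$pixels * 2.7
  wedge_img$pixels <- wedge_img$pixels * 2.7
  m2 <- analyze_acquisition(open_img, wedge_img)
  expect_equal(m2$wedge_factor, m1$wedge_factor, tolerance = 1e-12)
  expect_equal(m2$flatness_x, m1$flatness_x, tolerance = 1e-9)
  expect_equal(m2$size_x, m1$size_x, tolerance = 1e-9)
})

test_that("shift sensitivity is zero at zero offset and mirror-symmetric", {
  open_img <- generate_portal_image(beam_spec(seed = 40))$image
  wedge_img <- generate_portal_image(beam_spec(wedge = list(), seed = 41))$image
  scan <- shift_sensitivity(open_img, wedge_img, offsets = c(0, 2, 5, 10))
  zero <- dplyr::filter(scan, offset_mm == 0)
  expect_true(all(abs(zero$output_dev_pct) < 1e-9))
  expect_true(all(abs(zero$bq_dev_pct) < 1e-9))

  left <- dplyr::filter(scan, direction == "left")
  right <- dplyr::filter(scan, direction == "right")
  expect_equal(left$output_dev_pct, right$output_dev_pct, tolerance = 1e-6)
})

test_that("FFF output deviation grows sharply beyond the 10 mm offsets", {
  fff <- generate_portal_image(beam_spec(beam_type = "fff", seed = 42))$image
  scan <- shift_sensitivity(fff, offsets = c(1:10, 15))
  for (dir in unique(scan$direction)) {
    d <- dplyr::filter(scan, direction == dir)
    at15 <- abs(d$output_dev_pct[d$offset_mm == 15])
    expect_true(all(abs(d$output_dev_pct[d$offset_mm <= 10]) < at15))
  }
  # deviations are negative: the ROI slides down the FFF cone
  expect_true(all(scan$output_dev_pct < 0))
})

test_that("an ROI pushed off the panel is flagged, not fatal", {
  img <- generate_portal_image(small_spec(field_x = 60, field_y = 60, seed = 43))$image
  scan <- shift_sensitivity(img, offsets = c(5, 200))
  expect_true(all(scan$flagged[scan$offset_mm == 200]))
  expect_false(any(scan$flagged[scan$offset_mm == 5]))
  expect_identical(nrow(scan), 8L)
})

test_that("collimator-opposed pairs average to the radiation centre", {
  img <- generate_portal_image(beam_spec(shift_x = 1.5, seed = 44))$image
  same <- collimator_pair_center(img, img)
  g <- field_geometry(img)
  expect_equal(unname(same["x"]), g$center_x)

  pair <- generate_collimator_pair(beam_spec(shift_x = 2, shift_y = -1, seed = 45))
  ctr <- collimator_pair_center(pair$c90, pair$c270)
  expect_lt(abs(ctr["x"] - 2), HALF_PIXEL)
  expect_lt(abs(ctr["y"] - (-1)), HALF_PIXEL)
})

test_that("linearity fit recovers exact lines and is permutation invariant", {
  series <- tibble::tibble(mu_set = c(1, 5, 10, 50), mu_measured = 2 * c(1, 5, 10, 50) + 1)
  fit <- linearity_fit(series)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  perm <- linearity_fit(series[c(3, 1, 4, 2), ])
  expect_equal(perm$slope, fit$slope)
  expect_equal(perm$r_squared, fit$r_squared)

  expect_error(linearity_fit(series[1:2, ]), class = "epidqa_input_error")
  expect_error(
    linearity_fit(tibble::tibble(mu_set = c(5, 5, 5), mu_measured = 1:3)),
    class = "epidqa_input_error"
  )

  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  gl <- glance(fit)
  expect_equal(gl$r.squared, 1, tolerance = 1e-12)
})

test_that("noiseless MU ladders fit perfectly and recover the generator slope", {
  spec <- small_spec(seed = 46)
  for (ladder in list(mu_ladder_27(), mu_ladder_8())) {
    series <- generate_linearity_series(ladder, spec)
    tbl <- experiment_linearity_table(series)
    fit <- linearity_fit(tbl)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    # generator truth: mu = (mu_expected / MU) * MU exactly, intercept 0
    slope_true <- series[[1]]$truth$mu_expected / series[[1]]$image$mu
    expect_lt(abs(fit$slope / slope_true - 1), 5e-4)
    expect_lt(abs(fit$intercept), 1e-6 * max(tbl$mu_measured))
  }
})

test_that("long-term summaries report per-component mean and sd", {
  expect_error(long_term_summary(c(1)), class = "epidqa_input_error")

  const <- long_term_summary(c(1, 1, 1, 1))
  expect_equal(const$sd, 0)

  two <- long_term_summary(c(-1, 1))
  expect_equal(two$mean, 0)
  expect_equal(two$sd, sqrt(2))

  centres <- tibble::tibble(center_x = c(0.1, 0.3, 0.2), center_y = c(-1, 0, 1))
  s <- long_term_summary(centres)
  expect_identical(s$component, c("center_x", "center_y"))
  expect_equal(s$mean[1], 0.2)
  # translation equivariance of the mean
  s2 <- long_term_summary(dplyr::mutate(centres, center_x = center_x + 5))
  expect_equal(s2$mean[1], 5.2)
  expect_equal(s2$sd[1], s$sd[1])
})
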