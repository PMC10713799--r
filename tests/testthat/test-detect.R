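test_that("disc detection matches ground truth on a clean render", {
  sc <- make_scene(px_per_mm = 5)
  det <- detect_discs(sc$photo, sc$spec)
  expect_named(det, c("blue", "green", "red"), ignore.order = TRUE)
  for (col in names(det)) {
    expect_lt(pixel_distance(det[[col]]$centroid,
                             sc$photo$truth$landmark_truth[[col]]), 0.5)
    expect_gt(det[[col]]$circularity, 0.8)
    expect_lte(det[[col]]$circularity, 1.1)
  }
})

test_that("a cropped frame raises frame_not_detected", {
  spec <- default_spec()
  ph <- render_frame_photo(spec, scene_truth(4), max_size_px = 250)
  expect_false(ph$truth$frame_visible)
  expect_error(detect_discs(ph, spec), class = "frame_not_detected")
})

test_that("a similar-sized red distractor raises ambiguous_detection", {
  spec <- default_spec()
  tr <- scene_truth(5)
  clean <- render_frame_photo(spec, tr)
  r_px <- spec$disc_diameter_mm / 2 * 5
  distract <- list(list(center_px = c(dim(clean$image)[2] - 40,
                                      dim(clean$image)[1] - 40),
                        radius_px = r_px, rgb = c(0.88, 0.16, 0.12)))
  ph <- render_frame_photo(spec, tr, distractors = distract)
  expect_error(detect_discs(ph, spec), class = "ambiguous_detection")
})

test_that("detection survives background clutter of other colors and noise", {
  spec <- default_spec()
  set.seed(31)
  # a small red speck (rejected by area), a big grey blob (rejected by
  # saturation), and pixel noise
  distract <- list(list(center_px = c(30, 30), radius_px = 3,
                        rgb = c(0.9, 0.1, 0.1)),
                   list(center_px = c(60, 160), radius_px = 25,
                        rgb = c(0.55, 0.55, 0.55)))
  ph <- render_frame_photo(spec, scene_truth(5, rotation_deg = 75),
                           noise_sd = 0.02, distractors = distract)
  det <- detect_discs(ph, spec)
  cal <- calibrate_from_discs(det, spec)
  expect_equal(cal$mm_per_px, 0.2, tolerance = 0.005)
})

test_that("macro calibration recovers scale, rotation-invariantly", {
  spec <- default_spec()
  # identity scale
  ph1 <- render_frame_photo(spec, scene_truth(px_per_mm = 2))
  cal1 <- calibrate_from_discs(detect_discs(ph1, spec), spec)
  expect_equal(cal1$mm_per_px, 0.5, tolerance = 0.0025)
  expect_lt(cal1$residual, 0.005)
  expect_false(cal1$mirrored)
  # scaled, rotated, mirrored
  ph2 <- render_frame_photo(spec, scene_truth(5, 30, mirrored = TRUE))
  cal2 <- calibrate_from_discs(detect_discs(ph2, spec), spec)
  expect_equal(cal2$mm_per_px, 0.2, tolerance = 0.001)
  expect_true(cal2$mirrored)
  # same scene at another rotation agrees within 0.2%
  ph3 <- render_frame_photo(spec, scene_truth(5, 211, mirrored = TRUE))
  cal3 <- calibrate_from_discs(detect_discs(ph3, spec), spec)
  expect_lt(abs(cal3$mm_per_px - cal2$mm_per_px) / cal2$mm_per_px, 0.002)
})

test_that("scale recovery holds across seeded scenes", {
  spec <- default_spec()
  set.seed(17)
  for (i in 1:10) {
    s <- runif(1, 2, 20)
    ph <- render_frame_photo(spec, scene_truth(s, runif(1, 0, 360),
                                               mirrored = i %% 2 == 0))
    cal <- calibrate_from_discs(detect_discs(ph, spec), spec)
    expect_lt(abs(cal$mm_per_px - 1 / s) * s, 0.005)
    expect_identical(cal$mirrored, i %% 2 == 0)
  }
})

test_that("anisotropic stretch is flagged as inconsistent calibration", {
  spec <- default_spec()
  ph <- render_frame_photo(spec, scene_truth(5, rotation_deg = 10,
                                             stretch_x = 1.10))
  det <- detect_discs(ph, spec)
  expect_error(calibrate_from_discs(det, spec),
               class = "calibration_inconsistent")
})

test_that("manual grid calibration is exact and rejects degenerate clicks", {
  expect_equal(calibrate_manual(c(0, 0), c(100, 0), 50)$mm_per_px, 0.5)
  expect_error(calibrate_manual(c(3, 3), c(3, 3), 40),
               class = "degenerate_input")
  # on a render: 4 grid squares (40 mm) at 5 px/mm
  sc <- make_scene(px_per_mm = 5, rotation_deg = 18)
  gp <- grid_points_px(sc$photo$truth)
  cal <- calibrate_manual(gp$a, gp$b, gp$mm)
  expect_equal(cal$mm_per_px, 0.2, tolerance = 0.001)
  expect_identical(cal$method, "manual")
  expect_true(is.na(cal$residual))
  # manual agrees with macro within 0.5%
  macro <- calibrate_from_discs(detect_discs(sc$photo, sc$spec), sc$spec)
  expect_lt(abs(cal$mm_per_px - macro$mm_per_px) / macro$mm_per_px, 0.005)
})
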