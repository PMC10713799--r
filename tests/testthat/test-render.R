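test_that("rendered disc positions follow the stated transform", {
  spec <- default_spec()
  # identity-ish transform: truth pixel position equals mm position + offset,
  # and the imaged blue disc centroid matches the truth within half a pixel
  ph1 <- render_frame_photo(spec, scene_truth(px_per_mm = 2))
  det1 <- detect_discs(ph1, spec)
  for (col in c("blue", "red", "green")) {
    expect_lt(pixel_distance(det1[[col]]$centroid,
                             ph1$truth$landmark_truth[[col]]), 0.5)
  }
  # scaled + rotated: pixel separation of disc truths = scale x mm separation
  ph <- render_frame_photo(spec, scene_truth(px_per_mm = 5,
                                             rotation_deg = 30))
  d_px <- pixel_distance(ph$truth$landmark_truth$blue,
                         ph$truth$landmark_truth$red)
  d_mm <- pixel_distance(spec$disc_centers_mm$blue, spec$disc_centers_mm$red)
  expect_lt(abs(d_px - 5 * d_mm) / (5 * d_mm), 0.005)
})

test_that("mirroring flips the orientation of the disc triangle", {
  spec <- default_spec()
  area_of <- function(mirrored) {
    ph <- render_frame_photo(spec, scene_truth(3, 20, mirrored = mirrored))
    p <- ph$truth$landmark_truth
    trismometry:::triangle_signed_area(p$blue, p$red, p$green)
  }
  a <- area_of(FALSE)
  b <- area_of(TRUE)
  expect_gt(a * b, -Inf)
  expect_true(sign(a) != sign(b))
  expect_equal(abs(a), abs(b), tolerance = 1e-9)
})

test_that("mouth landmarks encode the requested opening and width", {
  tr <- realize <- scene_truth(px_per_mm = 10)
  lm <- render_mouth_landmarks(35, 17, tr)
  expect_equal(pixel_distance(lm$upper_incisal, lm$lower_incisal), 350)
  expect_equal(pixel_distance(lm$upper_right_distal, lm$upper_left_distal),
               170)
  # zero opening: incisal points coincide
  lm0 <- render_mouth_landmarks(0, 17, tr)
  expect_equal(lm0$upper_incisal, lm0$lower_incisal)
})

test_that("calibrate-then-measure round-trips a noise-free scene", {
  sc <- make_scene(px_per_mm = 7.3, rotation_deg = 12,
                   opening = 30, width = 17)
  cal <- calibrate_from_discs(detect_discs(sc$photo, sc$spec), sc$spec)
  q <- measure_quantities(sc$landmarks, cal)
  expect_equal(q$opening_mm, 30, tolerance = 1e-3)
  expect_equal(q$incisor_width_mm, 17, tolerance = 1e-3)
})

test_that("distances are invariant under mirroring", {
  for (mir in c(FALSE, TRUE)) {
    lm <- render_mouth_landmarks(28, 16.5, scene_truth(6, 45, mirrored = mir))
    expect_equal(pixel_distance(lm$upper_incisal, lm$lower_incisal),
                 6 * 28, tolerance = 1e-9)
  }
})

test_that("oversized scenes are cropped and flagged as frame-not-visible", {
  spec <- default_spec()
  ph <- render_frame_photo(spec, scene_truth(px_per_mm = 4),
                           max_size_px = 250)
  expect_false(ph$truth$frame_visible)
  expect_lte(dim(ph$image)[1], 250)
  expect_lte(dim(ph$image)[2], 250)
  # uncropped render is visible
  expect_true(render_frame_photo(spec,
                                 scene_truth(4))$truth$frame_visible)
})

test_that("renders and landmark jitter are reproducible under a seed", {
  spec <- default_spec()
  img <- function() {
    set.seed(11)
    render_frame_photo(spec, scene_truth(2), background = "textured",
                       noise_sd = 0.02)$image
  }
  expect_identical(img(), img())
  jit <- function() {
    set.seed(12)
    render_mouth_landmarks(30, 17, scene_truth(5), jitter_sd_px = 2)
  }
  expect_identical(jit(), jit())
})

test_that("photos round-trip through PNG at 8-bit precision", {
  sc <- make_scene(px_per_mm = 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_photo_png(sc$photo, path)
  back <- read_photo_png(path)
  expect_equal(dim(back), dim(sc$photo$image))
  expect_lt(max(abs(back - sc$photo$image)), 1 / 255)
})
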