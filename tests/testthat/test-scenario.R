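# A noise-free baseline/follow-up pair rendered at different scales and
# rotations; every scenario must recover the same ground-truth opening.
make_pair <- function(opening = 30, width = 17) {
  spec <- default_spec()
  base_ph <- render_frame_photo(spec, scene_truth(7, rotation_deg = 3))
  base <- photo_bundle(render_mouth_landmarks(28, width, base_ph$truth,
                                              photo_id = "base"),
                       image = base_ph)
  fu_ph <- render_frame_photo(spec, scene_truth(5.5, rotation_deg = -14))
  fu <- photo_bundle(render_mouth_landmarks(opening, width, fu_ph$truth,
                                            photo_id = "fu"),
                     image = fu_ph,
                     grid_points = grid_points_px(fu_ph$truth))
  list(spec = spec, base = base, fu = fu)
}

test_that("all six scenarios recover the truth on noise-free scenes", {
  pair <- make_pair(opening = 30, width = 17)
  for (sc in paste0("M", 1:6)) {
    rec <- run_scenario(pair$fu, sc, pair$spec, baseline = pair$base,
                        ruler_width_mm = 17, participant_id = 1,
                        position_id = 1)
    expect_identical(rec$method, sc)
    expect_true(is.na(rec$excluded_reason))
    expect_equal(rec$opening_mm, 30, tolerance = 0.011)
  }
})

test_that("scenario input contracts are enforced", {
  pair <- make_pair()
  no_frame <- photo_bundle(pair$fu$landmarks)
  expect_error(run_scenario(no_frame, "M1", pair$spec),
               class = "scenario_input_error")
  expect_error(run_scenario(no_frame, "M6", pair$spec),
               class = "scenario_input_error")
  expect_error(run_scenario(pair$fu, "M2", pair$spec),
               class = "scenario_input_error")
  expect_error(run_scenario(pair$fu, "M3", pair$spec),
               class = "scenario_input_error")
})

test_that("batch processing records exclusions instead of crashing", {
  spec <- default_spec()
  bundles <- list()
  for (i in 1:6) {
    ph <- render_frame_photo(spec, scene_truth(4, rotation_deg = 10 * i))
    bundles[[i]] <- photo_bundle(render_mouth_landmarks(30, 17, ph$truth),
                                 image = ph)
  }
  # two photos with the frame cropped out of the picture
  for (i in 7:8) {
    ph <- render_frame_photo(spec, scene_truth(4), max_size_px = 250)
    bundles[[i]] <- photo_bundle(render_mouth_landmarks(30, 17, ph$truth),
                                 image = ph)
  }
  # one with ambiguous red clutter
  ph9 <- render_frame_photo(spec, scene_truth(5),
                            distractors = list(list(
                              center_px = c(30, 290), radius_px = 20,
                              rgb = c(0.9, 0.12, 0.1))))
  bundles[[9]] <- photo_bundle(render_mouth_landmarks(30, 17, ph9$truth),
                               image = ph9)
  # one with missing incisal landmarks
  ph10 <- render_frame_photo(spec, scene_truth(4))
  bundles[[10]] <- photo_bundle(landmark_set("p10"), image = ph10)

  out <- run_scenario_batch(bundles, "M1", spec)
  expect_equal(nrow(out), 10)
  expect_equal(sum(is.na(out$excluded_reason)), 6)
  expect_equal(sum(out$excluded_reason == "frame_not_in_picture",
                   na.rm = TRUE), 2)
  expect_equal(sum(out$excluded_reason == "background_noise", na.rm = TRUE), 1)
  expect_equal(sum(out$excluded_reason == "incisors_not_captured",
                   na.rm = TRUE), 1)
  expect_true(all(is.na(out$opening_mm) == !is.na(out$excluded_reason)))
})

test_that("selfie degradation widens differences more than portrait reuse", {
  # M2 and M4 share calibration logic; selfies differ only through lower
  # resolution and heavier annotation jitter, which must inflate the spread
  # of differences from the gold standard.
  spec <- default_spec()
  set.seed(41)
  n <- 40
  d_m2 <- d_m4 <- numeric(n)
  base_ph <- render_frame_photo(spec, scene_truth(8))
  base_cal <- calibrate_from_discs(detect_discs(base_ph, spec), spec)
  for (i in seq_len(n)) {
    opening <- runif(1, 20, 35)
    width <- 17
    base_lm <- render_mouth_landmarks(28, width, base_ph$truth,
                                      jitter_sd_px = 1)
    ref_mm <- measure_quantities(base_lm, base_cal,
                                 "incisor_width")$incisor_width_mm
    m1 <- opening   # gold standard, noise-free reference value
    measure_ref <- function(px_per_mm, jitter) {
      lm <- render_mouth_landmarks(opening, width, scene_truth(px_per_mm),
                                   jitter_sd_px = jitter)
      wpx <- pixel_distance(lm$upper_right_distal, lm$upper_left_distal)
      cal <- calibration_from_reference_width(wpx, ref_mm, "macro_baseline")
      measure_quantities(lm, cal, "opening")$opening_mm
    }
    d_m2[i] <- m1 - measure_ref(8, 1)    # portrait follow-up
    d_m4[i] <- m1 - measure_ref(4, 2.5)  # selfie follow-up
  }
  expect_gt(sd(d_m4), sd(d_m2))
})

test_that("ruler records carry the clinical rounding", {
  rec <- ruler_record(31.5, participant_id = 4, position_id = 2)
  expect_identical(rec$opening_mm, 32)
  expect_identical(rec$method, "ruler")
})
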