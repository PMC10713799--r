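#' Bundle the inputs belonging to one photograph
#'
#' A photo bundle groups everything the scenario pipeline may need for a
#' single photograph: the image itself (required when the frame must be
#' detected in it), the landmark annotations, and -- for manual grid
#' calibration -- two annotated grid points of known separation.
#'
#' @param landmarks A [landmark_set()], or `NULL`.
#' @param image A height x width x 3 RGB array or `frame_photo`, or `NULL`.
#' @param grid_points For manual calibration: a list with `a` and `b` (pixel
#'   points) and `mm` (their true separation in millimetres), or `NULL`.
#' @param photo_id Identifier; defaults to the landmark set's.
#' @return An object of class `photo_bundle`.
#' @export
photo_bundle <- function(landmarks = NULL, image = NULL, grid_points = NULL,
                         photo_id = NULL) {
  if (!is.null(landmarks)) stopifnot(inherits(landmarks, "landmark_set"))
  if (is.null(photo_id) && !is.null(landmarks)) photo_id <- landmarks$photo_id
  structure(list(photo_id = photo_id, landmarks = landmarks, image = image,
                 grid_points = grid_points),
            class = "photo_bundle")
}

scenario_calibration_method <- c(M1 = "macro", M2 = "reference_width",
                                 M3 = "ruler_width", M4 = "reference_width",
                                 M5 = "ruler_width", M6 = "manual")

#' Run one measurement scenario on a photo pair
#'
#' The six scenarios differ in which photo is calibrated and how:
#' \describe{
#'   \item{M1}{gold standard; the follow-up is a portrait with frame and is
#'     macro-calibrated directly from its detected discs.}
#'   \item{M2}{follow-up portrait without frame, calibrated by the incisor
#'     width measured on a macro-calibrated baseline photo with frame.}
#'   \item{M3}{follow-up portrait without frame, calibrated by a clinical
#'     ruler reading of the incisor width.}
#'   \item{M4/M5}{as M2/M3 but the follow-up is a selfie. Selfies differ
#'     only in image quality (resolution, annotation jitter) and mirroring;
#'     mirroring needs no correction because distances are
#'     reflection-invariant, so M4/M5 share the M2/M3 code path.}
#'   \item{M6}{follow-up portrait with frame, manually calibrated from two
#'     grid points of known separation.}
#' }
#'
#' Input-contract violations (a scenario given the wrong inputs) raise a
#' `scenario_input_error`. Pipeline failures on an individual photo --
#' frame not detected, ambiguous background clutter, inconsistent
#' calibration, landmarks missing -- do not raise: they are recorded in the
#' returned record's `excluded_reason`, mirroring the per-image exclusion
#' accounting of a real study batch.
#'
#' @param followup [photo_bundle()] of the photo to be measured. Must carry
#'   an image for M1 and grid points for M6; landmarks always.
#' @param scenario One of `"M1"` ... `"M6"`.
#' @param spec Frame geometry.
#' @param baseline [photo_bundle()] of the baseline portrait with frame
#'   (image + landmarks); required for M2 and M4.
#' @param ruler_width_mm Clinical ruler reading of the incisor width, mm;
#'   required for M3 and M5.
#' @param participant_id,position_id Identifiers copied into the record.
#' @param detect_args Extra arguments passed to [detect_discs()].
#' @return A one-row `data.frame` (a measurement record) with columns
#'   `participant_id`, `position_id`, `method`, `opening_mm`,
#'   `incisor_width_mm`, `calibration_method`, `excluded_reason`.
#' @export
run_scenario <- function(followup, scenario, spec = frame_spec(),
                         baseline = NULL, ruler_width_mm = NULL,
                         participant_id = NA, position_id = NA,
                         detect_args = list()) {
  stopifnot(inherits(followup, "photo_bundle"))
  scenario <- match.arg(scenario, paste0("M", 1:6))
  if (scenario == "M1" && is.null(followup$image)) {
    stop_scenario_input("M1 needs a follow-up photo with the frame in it")
  }
  if (scenario == "M6" && is.null(followup$grid_points)) {
    stop_scenario_input("M6 needs two annotated grid points on the follow-up")
  }
  if (scenario %in% c("M2", "M4") &&
      (is.null(baseline) || is.null(baseline$image) ||
         is.null(baseline$landmarks))) {
    stop_scenario_input(sprintf(
      "%s needs a baseline frame photo with landmarks", scenario))
  }
  if (scenario %in% c("M3", "M5") && is.null(ruler_width_mm)) {
    stop_scenario_input(sprintf(
      "%s needs a clinical ruler reading of the incisor width", scenario))
  }

  record <- data.frame(participant_id = participant_id,
                       position_id = position_id,
                       method = scenario,
                       opening_mm = NA_real_,
                       incisor_width_mm = NA_real_,
                       calibration_method = scenario_calibration_method[[scenario]],
                       excluded_reason = NA_character_)

  result <- tryCatch({
    cal <- switch(scenario,
      M1 = do.call(calibrate_from_discs,
                   c(list(do.call(detect_discs,
                                  c(list(followup$image, spec), detect_args)),
                          spec))),
      M6 = calibrate_manual(followup$grid_points$a, followup$grid_points$b,
                            followup$grid_points$mm),
      {
        # M2-M5: anatomical reference width
        ref_mm <- if (scenario %in% c("M2", "M4")) {
          base_cal <- calibrate_from_discs(
            do.call(detect_discs,
                    c(list(baseline$image, spec), detect_args)), spec)
          measure_quantities(baseline$landmarks, base_cal,
                             "incisor_width")$incisor_width_mm
        } else {
          ruler_width_mm
        }
        width_px <- pixel_distance(followup$landmarks$upper_right_distal,
                                   followup$landmarks$upper_left_distal)
        calibration_from_reference_width(
          width_px, ref_mm,
          source = if (scenario %in% c("M3", "M5")) "ruler"
                   else "macro_baseline")
      })
    if (is.null(followup$landmarks)) {
      stop_incisors_not_captured("follow-up photo has no landmark annotations")
    }
    q <- measure_quantities(followup$landmarks, cal, "opening")
    w <- tryCatch(
      measure_quantities(followup$landmarks, cal,
                         "incisor_width")$incisor_width_mm,
      incisors_not_captured = function(e) NA_real_)
    list(opening = q$opening_mm, width = w)
  }, pipeline_failure = function(e) e)

  if (inherits(result, "condition")) {
    record$excluded_reason <- exclusion_reason_for(result)
  } else {
    record$opening_mm <- result$opening
    record$incisor_width_mm <- result$width
  }
  record
}

#' Run a scenario over a batch of photographs
#'
#' Applies [run_scenario()] to each element of a list of follow-up bundles,
#' never aborting on a bad photo: per-photo failures are recorded as
#' exclusion reasons in the output table.
#'
#' @param followups List of [photo_bundle()]s, optionally with
#'   `participant_id`/`position_id` attributes carried as list names.
#' @param scenario,spec,baseline,ruler_width_mm,detect_args As in
#'   [run_scenario()]; `baseline` and `ruler_width_mm` may be single values
#'   (recycled) or lists/vectors parallel to `followups`.
#' @return A `data.frame` with one measurement record per photo.
#' @export
run_scenario_batch <- function(followups, scenario, spec = frame_spec(),
                               baseline = NULL, ruler_width_mm = NULL,
                               detect_args = list()) {
  n <- length(followups)
  get_i <- function(x, i) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "photo_bundle")) return(x)
    if (is.list(x)) return(x[[i]])
    if (length(x) == n) return(x[[i]])
    x
  }
  records <- lapply(seq_len(n), function(i) {
    run_scenario(followups[[i]], scenario, spec,
                 baseline = get_i(baseline, i),
                 ruler_width_mm = get_i(ruler_width_mm, i),
                 participant_id = if (!is.null(names(followups)))
                   names(followups)[i] else i,
                 position_id = NA,
                 detect_args = detect_args)
  })
  do.call(rbind, records)
}

#' A clinical ruler reading as a measurement record
#'
#' Wraps a direct ruler measurement of the mouth opening (rounded to the
#' ruler's resolution) into the same record format the photographic
#' scenarios produce, so it can enter the agreement analyses as the
#' conventional comparator.
#'
#' @param opening_mm Ruler reading of the opening, mm.
#' @param participant_id,position_id Identifiers.
#' @param rounding_mm Ruler resolution (reading is rounded half-up to it).
#' @return A one-row measurement record `data.frame`.
#' @export
ruler_record <- function(opening_mm, participant_id = NA, position_id = NA,
                         rounding_mm = 1) {
  data.frame(participant_id = participant_id, position_id = position_id,
             method = "ruler",
             opening_mm = round_half_up(opening_mm, rounding_mm),
             incisor_width_mm = NA_real_,
             calibration_method = "ruler",
             excluded_reason = NA_character_)
}
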