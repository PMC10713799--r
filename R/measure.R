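#' Subpixel landmark annotations for one photograph
#'
#' Holds the pixel coordinates of the four anatomical points the method uses:
#' the incisal edges of the upper and lower left central incisors (their
#' separation is the mouth opening) and the distal edges of the two upper
#' central incisors (their separation is the incisor width, the anatomical
#' calibration reference). Any point may be absent (`NULL`), as happens when
#' the incisors are not sufficiently captured in a photo.
#'
#' @param photo_id Identifier of the annotated photograph.
#' @param upper_incisal,lower_incisal,upper_right_distal,upper_left_distal
#'   Numeric `c(x, y)` pixel coordinates (subpixel allowed) or `NULL`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(photo_id,
                         upper_incisal = NULL, lower_incisal = NULL,
                         upper_right_distal = NULL, upper_left_distal = NULL) {
  pts <- list(upper_incisal = upper_incisal, lower_incisal = lower_incisal,
              upper_right_distal = upper_right_distal,
              upper_left_distal = upper_left_distal)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.null(p)) {
      stopifnot(is.numeric(p), length(p) == 2, all(is.finite(p)))
      pts[[nm]] <- as.numeric(p)
    }
  }
  structure(c(list(photo_id = photo_id), pts), class = "landmark_set")
}

#' Euclidean distance between two pixel points
#'
#' @param p,q Numeric `c(x, y)` points.
#' @return Distance in pixels.
#' @examples
#' pixel_distance(c(0, 0), c(3, 4))
#' @export
pixel_distance <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 2, length(q) == 2,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

# Readings are reported to the nearest hundredth of a millimetre; rounding is
# half-up and applied only to the final reading.
round_half_up <- function(x, unit = 0.01) {
  floor(x / unit + 0.5) * unit
}

#' Measure mouth opening and incisor width from landmarks
#'
#' Converts pixel separations to millimetres through a calibration and rounds
#' the final readings half-up to 0.01 mm. The mouth opening is the distance
#' between the upper and lower incisal points; the incisor width is the
#' distance between the two upper distal points.
#'
#' @param landmarks A [landmark_set()].
#' @param cal A [calibration()] (any provenance).
#' @param quantities Which quantities to compute.
#' @return A list with `opening_mm` and/or `incisor_width_mm`.
#' @export
measure_quantities <- function(landmarks, cal,
                               quantities = c("opening", "incisor_width")) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(cal, "calibration"))
  quantities <- match.arg(quantities, several.ok = TRUE)
  out <- list()
  if ("opening" %in% quantities) {
    if (is.null(landmarks$upper_incisal) || is.null(landmarks$lower_incisal)) {
      stop_incisors_not_captured(
        "incisal edges not annotated: cannot measure mouth opening")
    }
    d <- pixel_distance(landmarks$upper_incisal, landmarks$lower_incisal)
    out$opening_mm <- round_half_up(d * cal$mm_per_px)
  }
  if ("incisor_width" %in% quantities) {
    if (is.null(landmarks$upper_right_distal) ||
        is.null(landmarks$upper_left_distal)) {
      stop_incisors_not_captured(
        "distal edges not annotated: cannot measure incisor width")
    }
    d <- pixel_distance(landmarks$upper_right_distal,
                        landmarks$upper_left_distal)
    out$incisor_width_mm <- round_half_up(d * cal$mm_per_px)
  }
  out
}

#' Calibrate from a known reference width
#'
#' When a follow-up photo has no reference frame, the incisor width serves as
#' the anatomical reference: the width in pixels on the new photo, divided
#' into a known width in millimetres, gives the scale. The known width comes
#' either from a macro-calibrated baseline photo with frame
#' (`source = "macro_baseline"`) or from a clinical ruler measurement
#' (`source = "ruler"`).
#'
#' @param measured_width_px Incisor width on the uncalibrated photo, pixels.
#' @param reference_width_mm Known incisor width, mm.
#' @param source Provenance of the reference width.
#' @return A [calibration()] with method `reference_width` or `ruler_width`.
#' @export
calibration_from_reference_width <- function(measured_width_px,
                                             reference_width_mm,
                                             source = c("macro_baseline",
                                                        "ruler")) {
  source <- match.arg(source)
  if (!is.numeric(measured_width_px) || measured_width_px <= 0 ||
      !is.numeric(reference_width_mm) || reference_width_mm <= 0) {
    stop_degenerate("reference-width calibration needs positive widths")
  }
  calibration(mm_per_px = reference_width_mm / measured_width_px,
              method = if (source == "ruler") "ruler_width" else
                "reference_width")
}
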