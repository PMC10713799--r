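# Classed conditions for the measurement pipeline. Batch processing catches
# the pipeline_failure subclasses and records them as exclusion reasons; plain
# input-contract violations are ordinary errors.

tm_stop <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "trismometry_error")))
}

stop_frame_not_detected <- function(message, color = NA_character_) {
  tm_stop(c("frame_not_detected", "pipeline_failure"), message, color = color)
}

stop_ambiguous_detection <- function(message, color = NA_character_) {
  tm_stop(c("ambiguous_detection", "pipeline_failure"), message, color = color)
}

stop_calibration_inconsistent <- function(message, residual = NA_real_) {
  tm_stop(c("calibration_inconsistent", "pipeline_failure"), message,
          residual = residual)
}

stop_incisors_not_captured <- function(message) {
  tm_stop(c("incisors_not_captured", "pipeline_failure"), message)
}

stop_scenario_input <- function(message) {
  tm_stop("scenario_input_error", message)
}

stop_degenerate <- function(message) {
  tm_stop("degenerate_input", message)
}

# Exclusion bookkeeping mirrors the per-image accounting used in remote
# photography studies: upload_error, background_noise, frame_not_in_picture,
# incisors_not_captured.
exclusion_reason_for <- function(cond) {
  if (inherits(cond, "frame_not_detected")) return("frame_not_in_picture")
  if (inherits(cond, "ambiguous_detection")) return("background_noise")
  if (inherits(cond, "calibration_inconsistent")) return("background_noise")
  if (inherits(cond, "incisors_not_captured")) return("incisors_not_captured")
  "upload_error"
}
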