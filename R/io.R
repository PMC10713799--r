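#' Read and write landmark annotation files
#'
#' Landmark files are JSON mappings of photo id to a mapping of landmark
#' name to `[x, y]` pixel coordinates:
#' `{"photo1": {"upper_incisal": [102.5, 88.0], ...}, ...}`.
#'
#' @param path File path.
#' @param sets A list of [landmark_set()]s (for writing).
#' @return `read_landmarks()` returns a named list of `landmark_set`s;
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(id) {
    pts <- lapply(raw[[id]], function(p) as.numeric(unlist(p)))
    do.call(landmark_set, c(list(photo_id = id), pts))
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(sets, path) {
  payload <- list()
  for (s in sets) {
    pts <- s[c("upper_incisal", "lower_incisal", "upper_right_distal",
               "upper_left_distal")]
    payload[[s$photo_id]] <- pts[!vapply(pts, is.null, logical(1))]
  }
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' Read and write long-format measurement tables
#'
#' Plain CSV with one reading per row; the column set matches what
#' [simulate_measurement_study()] and [run_scenario()] produce.
#'
#' @param df Measurement table.
#' @param path File path.
#' @return `read_measurements()` returns a `data.frame`;
#'   `write_measurements()` returns `path` invisibly.
#' @export
write_measurements <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  read.csv(path)
}

#' Summarise agreement against a gold standard, Table-style
#'
#' Convenience wrapper producing one row per comparator method: mean
#' difference with CI, limits of agreement with CIs, span and N -- the
#' columns of a method-comparison summary table.
#'
#' @param df Long measurement table.
#' @param gold Gold-standard method label.
#' @param comparators Character vector of comparator labels.
#' @param quantity Quantity to compare.
#' @param mode `"repeated"` (variance-components adjustment) or
#'   `"independent"`.
#' @param conf_level Confidence level.
#' @return A `data.frame` with one row per comparison.
#' @export
agreement_table <- function(df, gold = "M1",
                            comparators = c("M2", "M3", "M4", "M5", "M6",
                                            "ruler"),
                            quantity = "opening",
                            mode = c("repeated", "independent"),
                            conf_level = 0.95) {
  mode <- match.arg(mode)
  rows <- lapply(comparators, function(m) {
    diffs <- differences_from_measurements(df, gold = gold, comparator = m,
                                           quantity = quantity)
    res <- if (mode == "repeated") loa_repeated(diffs, conf_level)
           else loa_independent(diffs, conf_level)
    data.frame(comparison = paste(gold, "vs", m),
               mean_diff = res$mean_diff,
               mean_ci_lower = res$mean_ci[1], mean_ci_upper = res$mean_ci[2],
               loa_lower = res$loa_lower,
               loa_lower_ci_lower = res$loa_lower_ci[1],
               loa_lower_ci_upper = res$loa_lower_ci[2],
               loa_upper = res$loa_upper,
               loa_upper_ci_lower = res$loa_upper_ci[1],
               loa_upper_ci_upper = res$loa_upper_ci[2],
               span = res$span,
               n = res$n_observations)
  })
  do.call(rbind, rows)
}
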