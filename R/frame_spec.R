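#' Physical geometry of the calibration reference frame
#'
#' The reference frame is a hand-held card carrying a grey/white grid of known
#' pitch and three colored discs (blue, red, green) that act as fiducial
#' landmarks for automatic calibration. All dimensions are in millimetres, in
#' a frame coordinate system with the origin at the top-left corner of the
#' card, x rightward and y downward.
#'
#' The default geometry (10 mm grid pitch on a 100 x 60 mm card, 8 mm discs
#' at three corners) is a plausible hand-held size; the calibration method
#' itself is dimension-agnostic and every value can be overridden here or via
#' a config file ([read_frame_spec()]).
#'
#' @param grid_pitch_mm Side length of one grid square, mm. Must be positive.
#' @param disc_centers_mm Named list with entries `blue`, `red`, `green`,
#'   each a numeric `c(x, y)` position of a disc center in frame
#'   coordinates (mm). The three centers must be non-collinear and lie
#'   within the frame extent.
#' @param disc_diameter_mm Disc diameter, mm. Must be positive.
#' @param extent_mm Numeric `c(width, height)` of the card, mm.
#'
#' @return An object of class `frame_spec`.
#' @examples
#' spec <- frame_spec()
#' spec$disc_centers_mm$blue
#' @export
frame_spec <- function(grid_pitch_mm = 10,
                       disc_centers_mm = list(blue = c(10, 10),
                                              red = c(90, 10),
                                              green = c(10, 50)),
                       disc_diameter_mm = 8,
                       extent_mm = c(100, 60)) {
  stopifnot(is.numeric(grid_pitch_mm), length(grid_pitch_mm) == 1,
            grid_pitch_mm > 0,
            is.numeric(disc_diameter_mm), length(disc_diameter_mm) == 1,
            disc_diameter_mm > 0,
            is.numeric(extent_mm), length(extent_mm) == 2, all(extent_mm > 0))
  labels <- names(disc_centers_mm)
  if (!setequal(labels, c("blue", "red", "green")) || anyDuplicated(labels)) {
    stop("disc_centers_mm must have exactly the labels blue, red, green")
  }
  disc_centers_mm <- disc_centers_mm[c("blue", "red", "green")]
  for (p in disc_centers_mm) {
    stopifnot(is.numeric(p), length(p) == 2, all(is.finite(p)))
    if (any(p < 0) || p[1] > extent_mm[1] || p[2] > extent_mm[2]) {
      stop("disc centers must lie within the frame extent")
    }
  }
  if (abs(triangle_signed_area(disc_centers_mm$blue, disc_centers_mm$red,
                               disc_centers_mm$green)) < 1e-9) {
    stop("the three disc centers must be non-collinear")
  }
  structure(list(grid_pitch_mm = grid_pitch_mm,
                 disc_centers_mm = disc_centers_mm,
                 disc_diameter_mm = disc_diameter_mm,
                 extent_mm = extent_mm),
            class = "frame_spec")
}

# Signed area of triangle (a, b, c); sign encodes orientation in the y-down
# pixel/frame convention.
triangle_signed_area <- function(a, b, c) {
  0.5 * ((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2]))
}

#' @export
print.frame_spec <- function(x, ...) {
  cat("Reference frame:", x$extent_mm[1], "x", x$extent_mm[2], "mm,",
      "grid pitch", x$grid_pitch_mm, "mm,",
      "disc diameter", x$disc_diameter_mm, "mm\n")
  for (col in names(x$disc_centers_mm)) {
    cat(sprintf("  %-5s disc at (%g, %g) mm\n", col,
                x$disc_centers_mm[[col]][1], x$disc_centers_mm[[col]][2]))
  }
  invisible(x)
}

#' Read or write a frame-geometry config file
#'
#' The config is a JSON or YAML mapping with keys `grid_pitch_mm`,
#' `disc_centers_mm` (mapping of color label to `[x, y]`), `disc_diameter_mm`
#' and `extent_mm`. The format is chosen from the file extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path File path.
#' @param spec A [frame_spec()] object (for writing).
#' @return `read_frame_spec()` returns a `frame_spec`;
#'   `write_frame_spec()` returns `path` invisibly.
#' @export
read_frame_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  centers <- lapply(raw$disc_centers_mm, function(p) as.numeric(unlist(p)))
  frame_spec(grid_pitch_mm = raw$grid_pitch_mm,
             disc_centers_mm = centers,
             disc_diameter_mm = raw$disc_diameter_mm,
             extent_mm = as.numeric(unlist(raw$extent_mm)))
}

#' @rdname read_frame_spec
#' @export
write_frame_spec <- function(spec, path) {
  stopifnot(inherits(spec, "frame_spec"))
  payload <- unclass(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}
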