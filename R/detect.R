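#' Pixel-to-millimetre calibration of a photograph
#'
#' @param mm_per_px Scale, millimetres per pixel (> 0).
#' @param method Provenance: `macro` (automatic, from the detected fiducial
#'   discs), `manual` (two clicked points of known separation on the grid),
#'   `reference_width` (anatomical incisor-width reference from a
#'   macro-calibrated baseline) or `ruler_width` (incisor-width reference
#'   from a clinical ruler reading).
#' @param anisotropy Ratio of the larger to the smaller axis scale of the
#'   fitted transform (>= 1); a value well above 1 signals that the photo
#'   violates the similarity (frontal, undistorted) assumption. Only the
#'   macro method can estimate it; others carry `NA`.
#' @param mirrored Logical; `TRUE` when the disc triangle has flipped
#'   orientation relative to the physical frame (selfie reflection). `NA`
#'   for non-macro methods.
#' @param residual Worst relative disagreement among the three pairwise
#'   disc-distance scale estimates; `NA` for non-macro methods.
#' @return An object of class `calibration`.
#' @export
calibration <- function(mm_per_px,
                        method = c("macro", "manual", "reference_width",
                                   "ruler_width"),
                        anisotropy = NA_real_, mirrored = NA,
                        residual = NA_real_) {
  method <- match.arg(method)
  stopifnot(is.numeric(mm_per_px), length(mm_per_px) == 1,
            is.finite(mm_per_px), mm_per_px > 0)
  if (!is.na(anisotropy)) stopifnot(anisotropy >= 1)
  structure(list(mm_per_px = mm_per_px, method = method,
                 anisotropy = anisotropy, mirrored = mirrored,
                 residual = residual),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Calibration (%s): %.6g mm/px", x$method, x$mm_per_px))
  if (!is.na(x$residual)) {
    cat(sprintf(" | residual %.3g, anisotropy %.4g, mirrored %s",
                x$residual, x$anisotropy, x$mirrored))
  }
  cat("\n")
  invisible(x)
}

# Default HSV color windows for the three fiducial discs. Hue in degrees on a
# 0-360 wheel; the red window wraps through zero. Wide enough to tolerate
# phone-camera white balance, narrow enough to keep the labels separated.
#' @rdname detect_discs
#' @export
default_color_windows <- function() {
  list(blue = c(200, 260), green = c(90, 150), red = c(340, 20))
}

hue_in_window <- function(hue_deg, window) {
  lo <- window[1]
  hi <- window[2]
  if (lo <= hi) hue_deg >= lo & hue_deg <= hi
  else hue_deg >= lo | hue_deg <= hi   # window wraps through 0
}

#' Detect the three colored fiducial discs in a photograph
#'
#' Re-implements the automatic disc-finding step of frame-based photo
#' calibration: threshold the image in HSV space once per color label,
#' extract connected components, discard components that are too small or
#' insufficiently circular, and keep the best remaining component per color.
#'
#' Selection is deterministic: largest area wins; areas tied within 1 px^2
#' are broken by higher circularity, then by smaller (y, x) centroid. If no
#' component qualifies for some color, the frame is considered not to be in
#' the picture (`frame_not_detected`). If the two largest qualifying
#' components of one color have areas within `ambiguity_ratio` of each other,
#' background clutter is indistinguishable from the disc and the photo is
#' rejected (`ambiguous_detection`) rather than guessed at.
#'
#' @param image A height x width x 3 RGB array in 0-1, or a `frame_photo`.
#' @param spec Frame geometry (reserved for window auto-tuning; the default
#'   detection uses only the color labels).
#' @param color_windows Named list of hue windows in degrees, see
#'   [default_color_windows()].
#' @param sat_min,val_min Minimum HSV saturation and value for a pixel to
#'   count as colored.
#' @param min_area_frac Minimum component area as a fraction of image pixels.
#' @param min_circularity Minimum isoperimetric circularity
#'   4*pi*area/perimeter^2; discs score near 1, speckle and streaks lower.
#' @param ambiguity_ratio Two qualifying components of one color with areas
#'   within this relative band are reported as ambiguous.
#' @return A named list (blue, red, green) of `disc_detection` objects with
#'   fields `color`, `centroid` (subpixel `c(x, y)`), `area` and
#'   `circularity`.
#' @export
detect_discs <- function(image, spec = frame_spec(),
                         color_windows = default_color_windows(),
                         sat_min = 0.4, val_min = 0.25,
                         min_area_frac = 5e-4, min_circularity = 0.6,
                         ambiguity_ratio = 0.25) {
  if (inherits(image, "frame_photo")) image <- image$image
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  H <- dim(image)[1]
  W <- dim(image)[2]
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]),
                            maxColorValue = 1)
  hue <- matrix(hsv[1, ] * 360, H, W)
  sat <- matrix(hsv[2, ], H, W)
  val <- matrix(hsv[3, ], H, W)
  colored <- sat >= sat_min & val >= val_min
  min_area <- min_area_frac * H * W

  out <- list()
  for (col in names(color_windows)) {
    mask <- colored & hue_in_window(hue, color_windows[[col]])
    cands <- component_stats(mask)
    cands <- cands[cands$area >= min_area & cands$circ >= min_circularity, ,
                   drop = FALSE]
    if (nrow(cands) == 0) {
      stop_frame_not_detected(
        sprintf("no qualifying %s disc found in the image", col), color = col)
    }
    if (nrow(cands) >= 2) {
      a <- sort(cands$area, decreasing = TRUE)[1:2]
      if ((a[1] - a[2]) / a[1] <= ambiguity_ratio) {
        stop_ambiguous_detection(
          sprintf("two similar-sized %s components: background clutter", col),
          color = col)
      }
    }
    # deterministic winner: area, then circularity, then (y, x)
    ord <- order(-cands$area, -cands$circ, cands$cy, cands$cx)
    best <- cands[ord[1], ]
    out[[col]] <- structure(list(color = col,
                                 centroid = c(best$cx, best$cy),
                                 area = best$area,
                                 circularity = best$circ),
                            class = "disc_detection")
  }
  out
}

# Connected components (8-connected) of a logical mask with area, centroid
# and isoperimetric circularity from a traced outer-boundary perimeter.
component_stats <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab == 0) {
    return(data.frame(area = numeric(0), cx = numeric(0), cy = numeric(0),
                      circ = numeric(0)))
  }
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- ((idx - 1) %% nrow(mask)) + 1
  cols <- ((idx - 1) %/% nrow(mask)) + 1
  area <- tabulate(labs, nbins = nlab)
  cx <- tapply(cols, labs, mean)
  cy <- tapply(rows, labs, mean)
  circ <- vapply(seq_len(nlab), function(k) {
    per <- boundary_perimeter(lab == k)
    4 * pi * area[k] / per^2
  }, numeric(1))
  data.frame(area = area, cx = as.numeric(cx), cy = as.numeric(cy),
             circ = circ)
}

# Chain-code perimeter of the outer boundary (Moore tracing on the
# 8-connected component); diagonal steps weigh sqrt(2). Single pixels and
# other degenerate shapes get the perimeter of their bounding square.
boundary_perimeter <- function(comp) {
  nr <- nrow(comp)
  nc <- ncol(comp)
  idx <- which(comp)
  if (length(idx) <= 2) return(4 * sqrt(length(idx)))
  # pad with FALSE ring so neighbor lookups never leave the matrix
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- comp
  # start: topmost then leftmost foreground pixel; backtrack points left
  rs <- ((idx - 1) %% nr) + 1
  cs <- ((idx - 1) %/% nr) + 1
  top <- min(rs)
  left <- min(cs[rs == top])
  start <- c(top + 1, left + 1)
  # clockwise Moore neighborhood offsets (row, col), starting west
  nb <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
               ncol = 2, byrow = TRUE)
  step_len <- ifelse(abs(nb[, 1]) + abs(nb[, 2]) == 2, sqrt(2), 1)
  cur <- start
  back_dir <- 1L   # came from the west
  perim <- 0
  first_move <- NA_integer_
  max_steps <- 4 * length(idx) + 8
  for (s in seq_len(max_steps)) {
    found <- FALSE
    for (j in 0:7) {
      d <- ((back_dir - 1L + j) %% 8L) + 1L
      nxt <- cur + nb[d, ]
      if (m[nxt[1], nxt[2]]) {
        perim <- perim + step_len[d]
        # next scan starts from the neighbor before the one we moved to
        back_dir <- ((d - 3L) %% 8L) + 1L
        cur <- nxt
        if (is.na(first_move)) first_move <- d
        found <- TRUE
        break
      }
    }
    if (!found) return(4)   # isolated pixel among diagonal-only neighbors
    if (all(cur == start) && s > 1) break
  }
  max(perim, 4)
}

#' Derive the automatic (macro) calibration from the detected discs
#'
#' The three pairwise pixel distances between disc centroids, divided by
#' their known millimetre separations on the physical frame, give three
#' independent scale estimates. Their mean defines the calibration; their
#' worst relative deviation from the mean is the residual, a diagnostic for
#' tilt or perspective. Orientation (mirroring) is read off the sign of the
#' disc-triangle cross product, and anisotropy from the singular values of
#' the affine transform fitted exactly through the three point pairs.
#'
#' @param detections Named list of the three `disc_detection`s (from
#'   [detect_discs()]).
#' @param spec Frame geometry giving the true disc separations.
#' @param residual_tol Maximum acceptable residual; beyond it the photo is
#'   rejected as inconsistent with a frontal similarity view
#'   (`calibration_inconsistent`) and should be retaken.
#' @return A [calibration()] with method `"macro"`.
#' @export
calibrate_from_discs <- function(detections, spec = frame_spec(),
                                 residual_tol = 0.03) {
  stopifnot(all(c("blue", "red", "green") %in% names(detections)))
  px <- lapply(detections[c("blue", "red", "green")], `[[`, "centroid")
  mm <- spec$disc_centers_mm
  pairs <- list(c("blue", "red"), c("blue", "green"), c("red", "green"))
  scales <- vapply(pairs, function(pr) {
    pixel_distance(px[[pr[1]]], px[[pr[2]]]) /
      pixel_distance(mm[[pr[1]]], mm[[pr[2]]])
  }, numeric(1))
  s_mean <- mean(scales)
  residual <- max(abs(scales - s_mean)) / s_mean
  if (residual > residual_tol) {
    stop_calibration_inconsistent(
      sprintf(paste0("pairwise disc scales disagree by %.1f%% ",
                     "(tolerance %.1f%%): tilted or distorted photo"),
              100 * residual, 100 * residual_tol),
      residual = residual)
  }
  mirrored <- sign(triangle_signed_area(px$blue, px$red, px$green)) !=
    sign(triangle_signed_area(mm$blue, mm$red, mm$green))
  # exact affine through the three point pairs; singular values of its
  # linear part are the two axis scales
  D <- cbind(rbind(do.call(cbind, mm), 1))
  P <- do.call(cbind, px)
  Aff <- P %*% solve(D)           # 2 x 3: [A | t]
  sv <- svd(Aff[, 1:2])$d
  calibration(mm_per_px = 1 / s_mean, method = "macro",
              anisotropy = max(sv) / min(sv), mirrored = mirrored,
              residual = residual)
}

#' Manual grid calibration from two clicked points
#'
#' The fallback when automatic disc detection fails: the operator clicks two
#' grid intersections a known number of grid squares apart and supplies the
#' true separation in millimetres.
#'
#' @param point_a,point_b Pixel coordinates `c(x, y)` of the two points.
#' @param known_distance_mm True separation, mm (> 0).
#' @return A [calibration()] with method `"manual"`.
#' @examples
#' calibrate_manual(c(0, 0), c(100, 0), 50)  # 0.5 mm/px
#' @export
calibrate_manual <- function(point_a, point_b, known_distance_mm) {
  stopifnot(is.numeric(known_distance_mm), known_distance_mm > 0)
  d <- pixel_distance(point_a, point_b)
  if (d == 0) {
    stop_degenerate("manual calibration points coincide")
  }
  calibration(mm_per_px = known_distance_mm / d, method = "manual")
}
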