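#' Describe the camera geometry of a synthetic scene
#'
#' A scene truth holds the ground-truth similarity transform mapping frame
#' coordinates (mm) to pixel coordinates: an isotropic scale (`px_per_mm`), a
#' rotation, and optionally a mirror flip (a selfie-camera reflection). An
#' optional anisotropic stretch of the x axis is available to build negative
#' tests: it violates the similarity model that calibration assumes, and a
#' correct calibrator must flag it rather than return a scale.
#'
#' Pixel convention: origin at the top-left, x rightward, y downward, pixel
#' centers at integer coordinates; subpixel positions are real numbers.
#'
#' @param px_per_mm Image scale, pixels per millimetre (> 0).
#' @param rotation_deg In-plane rotation of the frame in the image, degrees.
#' @param mirrored Logical; `TRUE` reflects the scene (selfie camera).
#' @param stretch_x Extra scale factor applied to the frame x axis before
#'   rotation; 1 (default) keeps the transform a similarity.
#' @param margin_mm Blank margin around the frame in the rendered image, mm.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(px_per_mm, rotation_deg = 0, mirrored = FALSE,
                        stretch_x = 1, margin_mm = 6) {
  stopifnot(is.numeric(px_per_mm), px_per_mm > 0, is.finite(rotation_deg),
            is.logical(mirrored), stretch_x > 0, margin_mm >= 0)
  structure(list(px_per_mm = px_per_mm, rotation_deg = rotation_deg,
                 mirrored = mirrored, stretch_x = stretch_x,
                 margin_mm = margin_mm, realized = FALSE),
            class = "scene_truth")
}

# Fill in the concrete affine map px = A %*% mm + t for a given frame spec:
# A = s * R(theta) * diag(stretch_x * mirror, 1). The offset places the
# transformed frame bounding box at the requested margin.
realize_scene <- function(truth, spec) {
  if (isTRUE(truth$realized)) return(truth)
  th <- truth$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mir <- if (truth$mirrored) -1 else 1
  A <- truth$px_per_mm * R %*% diag(c(truth$stretch_x * mir, 1))
  ext <- spec$extent_mm
  corners <- cbind(c(0, 0), c(ext[1], 0), c(0, ext[2]), ext)
  pc <- A %*% corners
  margin_px <- truth$margin_mm * truth$px_per_mm
  offset <- c(margin_px + 1, margin_px + 1) - c(min(pc[1, ]), min(pc[2, ]))
  size <- ceiling(c(max(pc[1, ]) - min(pc[1, ]), max(pc[2, ]) - min(pc[2, ])) +
                    2 * margin_px)
  # pad small scenes so the image never drops below 200 px on the short side
  extra <- pmax(0, 200 - size)
  offset <- offset + floor(extra / 2)
  size <- size + extra
  truth$A <- A
  truth$offset <- offset
  truth$width_px <- size[1]
  truth$height_px <- size[2]
  truth$realized <- TRUE
  truth
}

#' Map frame-coordinate points (mm) to pixel coordinates under a scene truth
#'
#' @param truth A realized or unrealized [scene_truth()]; if unrealized,
#'   `spec` is used to realize it first.
#' @param points_mm A 2-row matrix or a single `c(x, y)` point in mm.
#' @param spec Frame geometry, used only to realize `truth` if needed.
#' @return A 2-row matrix of pixel coordinates.
#' @export
scene_to_px <- function(truth, points_mm, spec = frame_spec()) {
  truth <- realize_scene(truth, spec)
  p <- if (is.matrix(points_mm)) points_mm else matrix(points_mm, nrow = 2)
  truth$A %*% p + truth$offset
}

#' Render a synthetic photograph of the reference frame
#'
#' Draws the grey/white grid and the three colored fiducial discs under the
#' scene's ground-truth transform, over a white or cluttered background, with
#' optional additive Gaussian pixel noise. The returned object carries the
#' realized `scene_truth`, including the true pixel positions of the disc
#' centers, so detection and calibration can be scored against ground truth.
#'
#' If the image the scene requires exceeds `max_size_px` on either side it is
#' cropped to that size (anchored at the top-left); discs falling outside the
#' crop emulate a photograph in which the frame is not completely in the
#' picture, and `frame_visible` is set to `FALSE`.
#'
#' Background clutter and pixel noise consume random numbers from the current
#' RNG stream; seed the stream for reproducible renders.
#'
#' @param spec Frame geometry, a [frame_spec()].
#' @param truth Camera geometry, a [scene_truth()].
#' @param background `"white"` or `"textured"`; the textured option stamps
#'   random colored distractor blobs to emulate background clutter.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise on
#'   the 0-1 scale (applied per channel, clipped).
#' @param max_size_px Maximum image side length; larger renders are cropped.
#' @param distractors Optional list of explicit distractor blobs, each a list
#'   with `center_px` (`c(x, y)`), `radius_px` and `rgb` (length-3, 0-1).
#'   Stamped after the frame, as foreground clutter.
#' @param n_clutter Number of random blobs for the textured background.
#' @return A list of class `frame_photo` with elements `image` (height x
#'   width x 3 array, values in 0-1) and `truth` (realized scene truth with
#'   `landmark_truth`, the true disc-center pixel coordinates, and
#'   `frame_visible`).
#' @examples
#' ph <- render_frame_photo(frame_spec(), scene_truth(px_per_mm = 2))
#' dim(ph$image)
#' ph$truth$landmark_truth$blue
#' @export
render_frame_photo <- function(spec, truth, background = c("white", "textured"),
                               noise_sd = 0, max_size_px = 4000,
                               distractors = NULL, n_clutter = 12) {
  stopifnot(inherits(spec, "frame_spec"), inherits(truth, "scene_truth"))
  background <- match.arg(background)
  truth <- realize_scene(truth, spec)
  W <- min(truth$width_px, max_size_px)
  H <- min(truth$height_px, max_size_px)

  # inverse map pixel centers -> mm
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  Ainv <- solve(truth$A)
  dx <- X - truth$offset[1]
  dy <- Y - truth$offset[2]
  mmx <- Ainv[1, 1] * dx + Ainv[1, 2] * dy
  mmy <- Ainv[2, 1] * dx + Ainv[2, 2] * dy

  img <- array(1, dim = c(H, W, 3))
  if (background == "textured") {
    for (i in seq_len(n_clutter)) {
      img <- stamp_blob(img,
                        center = c(stats::runif(1, 1, W), stats::runif(1, 1, H)),
                        radius = stats::runif(1, 0.01, 0.06) * min(W, H),
                        col = hsv_col(stats::runif(1, 0, 1),
                                      stats::runif(1, 0.3, 1),
                                      stats::runif(1, 0.3, 1)),
                        X = X, Y = Y)
    }
  }

  # grid: grey/white checkerboard over the frame extent
  ext <- spec$extent_mm
  in_frame <- mmx >= 0 & mmx <= ext[1] & mmy >= 0 & mmy <= ext[2]
  checker <- (floor(mmx / spec$grid_pitch_mm) +
                floor(mmy / spec$grid_pitch_mm)) %% 2 == 0
  shade <- ifelse(checker, 1, 0.62)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[in_frame] <- shade[in_frame]
    img[, , ch] <- plane
  }

  disc_rgb <- list(blue = c(0.10, 0.20, 0.90),
                   red = c(0.90, 0.15, 0.10),
                   green = c(0.10, 0.80, 0.20))
  r_mm <- spec$disc_diameter_mm / 2
  landmark_truth <- list()
  for (col in names(spec$disc_centers_mm)) {
    cmm <- spec$disc_centers_mm[[col]]
    inside <- (mmx - cmm[1])^2 + (mmy - cmm[2])^2 <= r_mm^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- disc_rgb[[col]][ch]
      img[, , ch] <- plane
    }
    landmark_truth[[col]] <- drop(scene_to_px(truth, cmm, spec))
  }

  if (!is.null(distractors)) {
    for (d in distractors) {
      img <- stamp_blob(img, d$center_px, d$radius_px, d$rgb, X, Y)
    }
  }

  if (noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }

  disc_r_px <- r_mm * truth$px_per_mm * max(truth$stretch_x, 1)
  frame_visible <- all(vapply(landmark_truth, function(p) {
    p[1] - disc_r_px >= 0.5 && p[1] + disc_r_px <= W + 0.5 &&
      p[2] - disc_r_px >= 0.5 && p[2] + disc_r_px <= H + 0.5
  }, logical(1)))
  truth$landmark_truth <- landmark_truth
  truth$frame_visible <- frame_visible
  truth$width_px <- W
  truth$height_px <- H
  structure(list(image = img, truth = truth), class = "frame_photo")
}

stamp_blob <- function(img, center, radius, col, X, Y) {
  inside <- (X - center[1])^2 + (Y - center[2])^2 <= radius^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

hsv_col <- function(h, s, v) {
  grDevices::col2rgb(grDevices::hsv(h, s, v))[, 1] / 255
}

#' Write a rendered photo to a PNG file
#'
#' @param photo A `frame_photo` (or bare height x width x 3 array in 0-1).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_photo_png <- function(photo, path) {
  img <- if (inherits(photo, "frame_photo")) photo$image else photo
  png::writePNG(img, path)
  invisible(path)
}

#' Read a photograph from a PNG file
#'
#' @param path PNG path.
#' @return A height x width x 3 array with values in 0-1.
#' @export
read_photo_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Place ground-truth mouth landmarks in a synthetic scene
#'
#' Generates the four anatomical landmarks used by the measurement pipeline -
#' the incisal edges of the upper and lower left central incisors (vertical
#' mouth-opening span) and the distal edges of the two upper central incisors
#' (horizontal incisor-width span) - at known millimetre geometry, mapped to
#' pixels through the scene's transform, with optional Gaussian placement
#' jitter emulating manual annotation error.
#'
#' @param opening_mm True interincisal distance, mm (>= 0).
#' @param incisor_width_mm True incisor width, mm (> 0).
#' @param truth A [scene_truth()] (realized with the default frame geometry
#'   if it has not been realized against a render).
#' @param jitter_sd_px SD of independent Gaussian jitter added to each pixel
#'   coordinate (uses the current RNG stream).
#' @param mouth_center_mm Position of the mouth center in frame coordinates;
#'   the default sits below the frame card. Distances are translation
#'   invariant, so the choice is cosmetic.
#' @param photo_id Identifier stored in the returned landmark set.
#' @return A [landmark_set()].
#' @export
render_mouth_landmarks <- function(opening_mm, incisor_width_mm, truth,
                                   jitter_sd_px = 0,
                                   mouth_center_mm = c(50, 100),
                                   photo_id = "synthetic") {
  stopifnot(opening_mm >= 0, incisor_width_mm > 0, jitter_sd_px >= 0)
  truth <- realize_scene(truth, frame_spec())
  cx <- mouth_center_mm[1]
  cy <- mouth_center_mm[2]
  up <- cy - opening_mm / 2
  pts_mm <- cbind(upper_incisal = c(cx, up),
                  lower_incisal = c(cx, cy + opening_mm / 2),
                  upper_right_distal = c(cx - incisor_width_mm / 2, up),
                  upper_left_distal = c(cx + incisor_width_mm / 2, up))
  pts_px <- scene_to_px(truth, pts_mm)
  if (jitter_sd_px > 0) {
    pts_px <- pts_px + matrix(rnorm(length(pts_px), 0, jitter_sd_px), 2)
  }
  landmark_set(photo_id = photo_id,
               upper_incisal = pts_px[, 1],
               lower_incisal = pts_px[, 2],
               upper_right_distal = pts_px[, 3],
               upper_left_distal = pts_px[, 4])
}
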