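# Shared fixture builders: everything is generated in code, no stored images.

default_spec <- function() frame_spec()

# A rendered frame photo plus noise-free landmarks for a given opening/width.
make_scene <- function(px_per_mm, rotation_deg = 0, mirrored = FALSE,
                       opening = 30, width = 17, jitter_sd_px = 0, ...) {
  spec <- default_spec()
  ph <- render_frame_photo(spec, scene_truth(px_per_mm, rotation_deg,
                                             mirrored), ...)
  lm <- render_mouth_landmarks(opening, width, ph$truth,
                               jitter_sd_px = jitter_sd_px)
  list(spec = spec, photo = ph, landmarks = lm)
}

# Two true grid intersections mapped to pixels, for manual calibration.
grid_points_px <- function(truth, a_mm = c(10, 30), b_mm = c(50, 30)) {
  list(a = drop(scene_to_px(truth, a_mm)),
       b = drop(scene_to_px(truth, b_mm)),
       mm = sqrt(sum((a_mm - b_mm)^2)))
}

# Differences drawn from the repeated-measures error model:
# d_ij = mu + b_i + e_ij, b ~ N(0, sb^2), e ~ N(0, sw^2).
simulate_differences <- function(n_subj, n_occ, mu, sb, sw) {
  b <- rnorm(n_subj, 0, sb)
  paired_differences(subject_id = rep(seq_len(n_subj), each = n_occ),
                     occasion_id = rep(seq_len(n_occ), n_subj),
                     diff_mm = mu + rep(b, each = n_occ) +
                       rnorm(n_subj * n_occ, 0, sw))
}

# Ratings for an ICC study: subject effect + rater effect + residual.
simulate_ratings <- function(n, k, subject_sd, resid_sd, rater_sd = 0,
                             mu = 25) {
  matrix(mu + rep(rnorm(n, 0, subject_sd), k) +
           rep(rnorm(k, 0, rater_sd), each = n) +
           rnorm(n * k, 0, resid_sd), n, k)
}
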