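#' Precision-based sample size for estimating an ICC
#'
#' Number of subjects (images) needed so that the confidence interval of an
#' anticipated intraclass correlation has a requested half-width, each
#' subject being rated `k` times. Uses Bonett's approximation: with `w` the
#' full CI width (`2 * ci_halfwidth`) and `z` the standard-normal quantile,
#'
#'   n = ceiling( 8 z^2 (1 - rho)^2 (1 + (k - 1) rho)^2 / (k (k - 1) w^2) + 1 )
#'
#' For example, an expected reliability of 0.9 estimated to a half-width of
#' 0.05 with three ratings per image needs 42 images.
#'
#' @param expected_icc Anticipated ICC, in (0, 1).
#' @param k_ratings Ratings per subject (>= 2).
#' @param ci_halfwidth Desired CI half-width, in (0, 1).
#' @param conf_level Confidence level.
#' @return Integer number of subjects.
#' @examples
#' icc_sample_size(0.9, 3, 0.05)  # 42
#' @export
icc_sample_size <- function(expected_icc, k_ratings, ci_halfwidth,
                            conf_level = 0.95) {
  stopifnot(expected_icc > 0, expected_icc < 1, k_ratings >= 2,
            ci_halfwidth > 0, ci_halfwidth < 1)
  if (ci_halfwidth >= 1 - expected_icc) {
    warning("requested half-width exceeds the distance from the expected ",
            "ICC to 1; the approximation is unreliable in this regime")
  }
  z <- qnorm((1 + conf_level) / 2)
  w <- 2 * ci_halfwidth
  n <- 8 * z^2 * (1 - expected_icc)^2 * (1 + (k_ratings - 1) * expected_icc)^2 /
    (k_ratings * (k_ratings - 1) * w^2) + 1
  as.integer(ceiling(n))
}

#' Precision of limits of agreement as a multiple of the SD
#'
#' The large-sample confidence interval of a 95% limit of agreement has
#' half-width `z * sqrt(3 / n) * SD`, where `n` is the number of
#' observations and SD the standard deviation of the between-method
#' differences. At `n = 100` the factor is 0.34: the limits are estimated to
#' about a third of the difference SD, the usual target for planning an
#' agreement study.
#'
#' @param n_observations Planned number of observations (>= 3).
#' @param conf_level Confidence level.
#' @return The dimensionless multiplier of the difference SD.
#' @examples
#' loa_ci_halfwidth_factor(100)  # ~0.34
#' @export
loa_ci_halfwidth_factor <- function(n_observations, conf_level = 0.95) {
  stopifnot(n_observations >= 3)
  z_mult(conf_level) * sqrt(3 / n_observations)
}

#' Participants needed to reach a target number of observations
#'
#' @param units_needed Total observations (images, readings) required.
#' @param units_per_participant Observations contributed per participant
#'   (e.g. 2 jaw positions each).
#' @return Integer number of participants (ceiling).
#' @examples
#' participants_required(42, 2)   # 21
#' participants_required(100, 2)  # 50
#' @export
participants_required <- function(units_needed, units_per_participant) {
  stopifnot(units_needed > 0, units_per_participant > 0)
  as.integer(ceiling(units_needed / units_per_participant))
}
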