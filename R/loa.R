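#' Build a paired-differences table
#'
#' The agreement analyses work on per-occasion differences between a gold
#' standard and a comparator method, with the sign convention gold standard
#' minus comparator: a negative mean difference means the comparator
#' overestimates.
#'
#' @param subject_id,occasion_id Vectors identifying the subject and the
#'   occasion (e.g. jaw position) of each difference.
#' @param diff_mm Differences, mm.
#' @param mean_mm Optional per-pair means of the two methods' readings
#'   (needed for Bland-Altman plots).
#' @return A `data.frame` of class `paired_differences`.
#' @export
paired_differences <- function(subject_id, occasion_id, diff_mm,
                               mean_mm = NULL) {
  stopifnot(length(subject_id) == length(diff_mm),
            length(occasion_id) == length(diff_mm),
            all(is.finite(diff_mm)))
  out <- data.frame(subject_id = subject_id, occasion_id = occasion_id,
                    diff_mm = diff_mm)
  if (!is.null(mean_mm)) out$mean_mm <- mean_mm
  class(out) <- c("paired_differences", "data.frame")
  out
}

#' Differences between two methods from a long measurement table
#'
#' Joins a gold-standard and a comparator method on participant x position
#' and returns gold-minus-comparator differences (dropping excluded or
#' missing readings), ready for [loa_repeated()] or [loa_independent()].
#'
#' @param df Long table with columns `participant_id`, `position_id`,
#'   `method`, `value_mm` and optionally `quantity`
#'   (as from [simulate_measurement_study()]) -- or `opening_mm` in place of
#'   `value_mm` (as from [run_scenario()]).
#' @param gold,comparator Method labels.
#' @param quantity Which quantity to compare when a `quantity` column exists.
#' @return A [paired_differences()] table with pair means attached.
#' @export
differences_from_measurements <- function(df, gold = "M1", comparator,
                                          quantity = "opening") {
  if (!"value_mm" %in% names(df) && "opening_mm" %in% names(df)) {
    df$value_mm <- df$opening_mm
  }
  if ("quantity" %in% names(df)) df <- df[df$quantity == quantity, ]
  g <- df[df$method == gold, c("participant_id", "position_id", "value_mm")]
  c_ <- df[df$method == comparator,
           c("participant_id", "position_id", "value_mm")]
  m <- merge(g, c_, by = c("participant_id", "position_id"),
             suffixes = c("_gold", "_comp"))
  m <- m[is.finite(m$value_mm_gold) & is.finite(m$value_mm_comp), ]
  paired_differences(subject_id = m$participant_id,
                     occasion_id = m$position_id,
                     diff_mm = m$value_mm_gold - m$value_mm_comp,
                     mean_mm = (m$value_mm_gold + m$value_mm_comp) / 2)
}

# The conventional LoA multiplier. 1.96 is used literally at the 95% level,
# matching standard Bland-Altman practice and precision planning arithmetic.
z_mult <- function(conf_level) {
  if (isTRUE(all.equal(conf_level, 0.95))) 1.96
  else qnorm((1 + conf_level) / 2)
}

loa_result <- function(mean_diff, mean_ci, sd_total, z, N, n_subjects, mode,
                       conf_level, sigma2_b = NA_real_, sigma2_w = NA_real_) {
  loa_lower <- mean_diff - z * sd_total
  loa_upper <- mean_diff + z * sd_total
  # precision of each limit: half-width z * sqrt(3/N) * SD
  hw <- z * sqrt(3 / N) * sd_total
  structure(list(mean_diff = mean_diff, mean_ci = mean_ci,
                 sd_total = sd_total,
                 loa_lower = loa_lower,
                 loa_lower_ci = c(loa_lower - hw, loa_lower + hw),
                 loa_upper = loa_upper,
                 loa_upper_ci = c(loa_upper - hw, loa_upper + hw),
                 span = loa_upper - loa_lower,
                 n_subjects = n_subjects, n_observations = N,
                 mode = mode, conf_level = conf_level,
                 sigma2_between = sigma2_b, sigma2_within = sigma2_w),
            class = "loa_result")
}

#' Limits of agreement for multiple observations per subject
#'
#' Bland and Altman's variance-components method for agreement studies in
#' which each subject contributes several occasions and the true value varies
#' between occasions. A one-way ANOVA of the differences on subject yields
#' the between-subject (`MSB`) and within-subject (`MSW`) mean squares; with
#' the unbalanced-design average group size
#'
#'   m0 = (N - sum(m_i^2) / N) / (n - 1),
#'
#' the between-subject variance component is
#' `sigma2_b = max(0, (MSB - MSW) / m0)`, the total SD of a single
#' difference is `sqrt(sigma2_b + MSW)`, and the limits of agreement are
#' mean +/- 1.96 x that SD. Negative variance-component estimates are
#' truncated at zero, so the total SD never falls below `sqrt(MSW)`.
#'
#' The confidence interval of each limit uses half-width
#' `1.96 * sqrt(3 / N) * SD` (the standard large-sample precision of a
#' limit of agreement, with N the total number of observations); the mean
#' difference's CI uses `1.96 * sqrt(sigma2_b / n + MSW / N)`.
#'
#' @param diffs A [paired_differences()] table.
#' @param conf_level Confidence level.
#' @return An object of class `loa_result`.
#' @export
loa_repeated <- function(diffs, conf_level = 0.95) {
  stopifnot(inherits(diffs, "data.frame"), nrow(diffs) >= 2)
  d <- diffs$diff_mm
  subj <- factor(diffs$subject_id)
  n <- nlevels(subj)
  if (n < 2) stop("need at least two subjects")
  m_i <- as.vector(table(subj))
  N <- length(d)
  if (all(m_i == 1)) {
    warning("every subject contributes a single occasion; ",
            "falling back to the independent-observations analysis")
    return(loa_independent(diffs, conf_level))
  }
  z <- z_mult(conf_level)
  grand <- mean(d)
  means_i <- tapply(d, subj, mean)
  SSB <- sum(m_i * (means_i - grand)^2)
  SSW <- sum((d - means_i[subj])^2)
  MSB <- SSB / (n - 1)
  MSW <- SSW / (N - n)
  m0 <- (N - sum(m_i^2) / N) / (n - 1)
  sigma2_b <- max(0, (MSB - MSW) / m0)
  sd_total <- sqrt(sigma2_b + MSW)
  mean_se <- sqrt(sigma2_b / n + MSW / N)
  loa_result(mean_diff = grand,
             mean_ci = grand + c(-1, 1) * z * mean_se,
             sd_total = sd_total, z = z, N = N, n_subjects = n,
             mode = "repeated_adjusted", conf_level = conf_level,
             sigma2_b = sigma2_b, sigma2_w = MSW)
}

#' Limits of agreement assuming independent observations
#'
#' The classical Bland-Altman analysis, ignoring any clustering of
#' observations within subjects: mean difference +/- 1.96 x the ordinary
#' sample SD over all differences. Used as the sensitivity analysis when the
#' number of observations per subject is small relative to the number of
#' subjects.
#'
#' @param diffs A [paired_differences()] table (>= 3 differences).
#' @param conf_level Confidence level.
#' @return An object of class `loa_result` with mode `"independent"`.
#' @export
loa_independent <- function(diffs, conf_level = 0.95) {
  stopifnot(inherits(diffs, "data.frame"))
  d <- diffs$diff_mm
  N <- length(d)
  if (N < 3) stop("need at least 3 differences")
  z <- z_mult(conf_level)
  s <- sd(d)
  loa_result(mean_diff = mean(d),
             mean_ci = mean(d) + c(-1, 1) * z * s / sqrt(N),
             sd_total = s, z = z, N = N,
             n_subjects = length(unique(diffs$subject_id)),
             mode = "independent", conf_level = conf_level)
}

#' Width of a limits-of-agreement interval
#'
#' @param result A `loa_result`.
#' @return `loa_upper - loa_lower`, mm.
#' @export
loa_span <- function(result) {
  stopifnot(inherits(result, "loa_result"))
  result$loa_upper - result$loa_lower
}

#' @export
print.loa_result <- function(x, digits = 2, ...) {
  f <- function(v) sprintf("%.*f", digits, v)
  cat(sprintf("Limits of agreement (%s mode), %d observations from %d subjects\n",
              x$mode, x$n_observations, x$n_subjects))
  cat(sprintf("  mean difference %s (%g%% CI %s, %s) mm\n",
              f(x$mean_diff), 100 * x$conf_level, f(x$mean_ci[1]),
              f(x$mean_ci[2])))
  cat(sprintf("  LoA %s (%s, %s), %s (%s, %s) mm; span %s mm\n",
              f(x$loa_lower), f(x$loa_lower_ci[1]), f(x$loa_lower_ci[2]),
              f(x$loa_upper), f(x$loa_upper_ci[1]), f(x$loa_upper_ci[2]),
              f(x$span)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of the per-occasion differences against the pairwise means, with
#' a solid line at the mean difference and dotted lines at the limits of
#' agreement.
#'
#' @param diffs A [paired_differences()] table carrying a `mean_mm` column.
#' @param result The `loa_result` whose lines to draw (defaults to
#'   [loa_repeated()] of `diffs`).
#' @param out_path Optional file path; if given the plot is saved there
#'   (format from the extension, e.g. `.png`).
#' @param title Optional plot title.
#' @return The ggplot object, invisibly.
#' @export
bland_altman_plot <- function(diffs, result = NULL, out_path = NULL,
                              title = NULL) {
  stopifnot(inherits(diffs, "data.frame"))
  if (nrow(diffs) == 0) stop("no differences to plot")
  if (!"mean_mm" %in% names(diffs)) {
    stop("diffs must carry a mean_mm column (pairwise means) for plotting")
  }
  if (is.null(result)) result <- loa_repeated(diffs)
  p <- ggplot2::ggplot(as.data.frame(diffs),
                       ggplot2::aes(x = mean_mm, y = diff_mm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = result$mean_diff, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(result$loa_lower, result$loa_upper),
                        linetype = "dotted", linewidth = 0.7) +
    ggplot2::labs(x = "Mean of the two methods (mm)",
                  y = "Difference, gold standard - comparator (mm)",
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 6, height = 4, dpi = 150)
  }
  invisible(p)
}
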