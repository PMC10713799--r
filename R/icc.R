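#' Intraclass correlation from a two-way random-effects model
#'
#' Estimates the single-measure, absolute-agreement ICC for a complete
#' subjects x raters (or occasions) matrix, the reliability coefficient for
#' repeated measurement of the same images. Both subjects and raters are
#' treated as random samples. With mean squares from the two-way ANOVA
#' (subjects `MSR`, raters `MSC`, residual `MSE`):
#'
#'   ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))
#'
#' The confidence interval uses the Satterthwaite-approximation F method
#' appropriate to this ICC form (McGraw & Wong's ICC(A,1)).
#'
#' Absolute agreement (rather than consistency) is the right form here:
#' repeated measurements of the same photograph must agree in value, not
#' merely rank, for the measurement to be called reliable.
#'
#' @param ratings Numeric matrix, subjects in rows, raters/occasions in
#'   columns; complete, `n >= 2` subjects and `k >= 2` columns.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `icc_result`: `icc`, `ci_lower`, `ci_upper`,
#'   `ms` (named mean squares), `n`, `k`, `conf_level`.
#' @examples
#' m <- cbind(a = c(9, 6, 8, 7, 10, 6), b = c(2, 1, 4, 1, 5, 2),
#'            c = c(5, 3, 6, 2, 6, 4))
#' icc_two_way_random(m)
#' @export
icc_two_way_random <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete (no NA cells)")
  n <- nrow(ratings)
  k <- ncol(ratings)
  stopifnot(n >= 2, k >= 2, conf_level > 0, conf_level < 1)
  grand <- mean(ratings)
  if (all(ratings == ratings[1])) {
    stop_degenerate("all ratings identical: total variance is zero, ICC undefined")
  }
  MSR <- k * var(rowMeans(ratings))
  MSC <- n * var(colMeans(ratings))
  SST <- sum((ratings - grand)^2)
  SSE <- SST - (n - 1) * MSR - (k - 1) * MSC
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  if (MSE <= .Machine$double.eps * MSR) {
    # perfect agreement: no residual variance, the interval collapses
    return(structure(list(icc = icc, ci_lower = icc, ci_upper = icc,
                          ms = c(subject = MSR, rater = MSC, residual = MSE),
                          n = n, k = k, conf_level = conf_level),
                     class = "icc_result"))
  }
  # Satterthwaite df for the F bounds (McGraw & Wong, ICC(A,1))
  alpha <- 1 - conf_level
  Fj <- MSC / MSE
  vn <- (k - 1) * (n - 1) *
    (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * Fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  FU <- qf(1 - alpha / 2, n - 1, v)
  FL <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FU * MSE) /
    (FU * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FL * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FL * MSR)
  lower <- max(-1, min(lower, icc))
  upper <- min(1, max(upper, icc))

  structure(list(icc = icc, ci_lower = lower, ci_upper = upper,
                 ms = c(subject = MSR, rater = MSC, residual = MSE),
                 n = n, k = k, conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Two-way random-effects ICC (absolute agreement, single measure)\n"))
  cat(sprintf("  ICC = %.*f (%g%% CI %.*f, %.*f)   n = %d subjects, k = %d\n",
              digits, x$icc, 100 * x$conf_level, digits, x$ci_lower,
              digits, x$ci_upper, x$n, x$k))
  invisible(x)
}

#' Arrange long-format ratings into a subjects-by-raters matrix
#'
#' @param df Data frame with subject, rater and value columns.
#' @param subject,rater,value Column names.
#' @return A numeric matrix suitable for [icc_two_way_random()].
#' @export
ratings_matrix <- function(df, subject = "subject_id", rater = "rater_id",
                           value = "value_mm") {
  m <- tapply(df[[value]], list(df[[subject]], df[[rater]]), mean)
  if (anyNA(m)) stop("ratings are incomplete: every subject needs a value ",
                     "for every rater")
  m
}
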