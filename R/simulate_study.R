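#' Parameters for a simulated method-comparison study
#'
#' Describes a validation study in which each participant holds a number of
#' fixed, restricted jaw positions and each position is measured by several
#' methods (the photographic scenarios `M1`-`M6` and a clinical `ruler`).
#' Every reading follows an additive error model:
#'
#'   reading = truth + bias_method + b(participant, method) + e(reading)
#'
#' with `b ~ N(0, between_subject_error_sd^2)` drawn once per
#' participant-method pair and `e ~ N(0, within_subject_error_sd^2)` per
#' reading. This is exactly the variance decomposition that the
#' repeated-measures limits-of-agreement analysis assumes, so the estimand of
#' [loa_repeated()] is recoverable by construction. Ruler readings are
#' additionally rounded half-up to `ruler_rounding_mm`, as a clinician
#' reading a millimetre ruler would.
#'
#' The default per-method biases place the simulated study in the regime
#' reported for this family of methods: frame-calibrated photographic methods
#' nearly unbiased, ruler-calibrated selfies overestimating by close to a
#' millimetre, and the clinical ruler overestimating the opening by about
#' 1.7 mm and the incisor width by about 0.9 mm.
#'
#' @param n_participants Number of participants.
#' @param positions_per_participant Fixed jaw positions per participant
#'   (readings of the opening per participant-method).
#' @param opening_mean,opening_sd Distribution of true openings across
#'   participant-positions, mm. Defaults emulate a restricted opening held
#'   on a bite block.
#' @param per_method_bias Named vector, systematic error of each method's
#'   opening reading, mm (bias of the comparator; the gold standard M1 is 0).
#' @param between_subject_error_sd,within_subject_error_sd Error components,
#'   mm (see model above).
#' @param incisor_width_mean,incisor_width_sd Distribution of true incisor
#'   widths across participants, mm.
#' @param width_bias Named vector, systematic error of the incisor-width
#'   readings for the methods that measure it.
#' @param ruler_rounding_mm Resolution of the clinical ruler, mm.
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @return An object of class `study_sim_params`.
#' @export
study_sim_params <- function(n_participants = 50,
                             positions_per_participant = 2,
                             opening_mean = 25, opening_sd = 6,
                             per_method_bias = c(M1 = 0, M2 = -0.16,
                                                 M3 = 0.39, M4 = 0.14,
                                                 M5 = 0.80, M6 = -0.01,
                                                 ruler = 1.72),
                             between_subject_error_sd = 0.6,
                             within_subject_error_sd = 0.6,
                             incisor_width_mean = 17, incisor_width_sd = 1.2,
                             width_bias = c(M1 = 0, ruler = 0.91),
                             ruler_rounding_mm = 1,
                             seed = 1L) {
  allowed <- c(paste0("M", 1:6), "ruler")
  bad <- setdiff(names(per_method_bias), allowed)
  if (length(bad) || is.null(names(per_method_bias))) {
    stop("unknown method key(s) in per_method_bias: ",
         paste(bad, collapse = ", "))
  }
  stopifnot(n_participants >= 1, positions_per_participant >= 1,
            opening_sd >= 0, between_subject_error_sd >= 0,
            within_subject_error_sd >= 0, incisor_width_sd >= 0,
            ruler_rounding_mm > 0,
            all(names(width_bias) %in% allowed))
  structure(list(n_participants = as.integer(n_participants),
                 positions_per_participant =
                   as.integer(positions_per_participant),
                 opening_mean = opening_mean, opening_sd = opening_sd,
                 per_method_bias = per_method_bias,
                 between_subject_error_sd = between_subject_error_sd,
                 within_subject_error_sd = within_subject_error_sd,
                 incisor_width_mean = incisor_width_mean,
                 incisor_width_sd = incisor_width_sd,
                 width_bias = width_bias,
                 ruler_rounding_mm = ruler_rounding_mm,
                 seed = as.integer(seed)),
            class = "study_sim_params")
}

#' Simulate a long-format measurement study
#'
#' Draws true openings and incisor widths, then generates one reading per
#' participant x position x method under the error model of
#' [study_sim_params()]. Deterministic given the seed in `params`.
#'
#' @param params A [study_sim_params()].
#' @return A long-format `data.frame` with columns `participant_id`,
#'   `position_id`, `method`, `quantity` (`opening` or `incisor_width`),
#'   `value_mm` and `true_mm` (the simulated ground truth, for scoring).
#'   Incisor-width rows appear once per participant (the width does not vary
#'   with jaw position) for the methods named in `width_bias`.
#' @examples
#' head(simulate_measurement_study(study_sim_params(n_participants = 3)))
#' @export
simulate_measurement_study <- function(params) {
  stopifnot(inherits(params, "study_sim_params"))
  withr::with_seed(params$seed, {
    n <- params$n_participants
    npos <- params$positions_per_participant
    methods <- names(params$per_method_bias)
    sb <- params$between_subject_error_sd
    sw <- params$within_subject_error_sd

    truth_open <- matrix(rnorm(n * npos, params$opening_mean,
                               params$opening_sd), n, npos)
    truth_open[truth_open < 0] <- 0
    truth_width <- rnorm(n, params$incisor_width_mean, params$incisor_width_sd)

    # participant-method error components, openings
    b_open <- matrix(rnorm(n * length(methods), 0, sb), n,
                     dimnames = list(NULL, methods))
    rows <- vector("list", 0)
    for (m in methods) {
      vals <- truth_open + params$per_method_bias[[m]] + b_open[, m] +
        matrix(rnorm(n * npos, 0, sw), n, npos)
      if (m == "ruler") vals <- round_half_up(vals, params$ruler_rounding_mm)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = rep(seq_len(n), times = npos),
        position_id = rep(seq_len(npos), each = n),
        method = m, quantity = "opening",
        value_mm = as.vector(vals), true_mm = as.vector(truth_open))
    }

    wmethods <- names(params$width_bias)
    if (length(wmethods)) {
      b_width <- matrix(rnorm(n * length(wmethods), 0, sb), n,
                        dimnames = list(NULL, wmethods))
      for (m in wmethods) {
        vals <- truth_width + params$width_bias[[m]] + b_width[, m] +
          rnorm(n, 0, sw)
        if (m == "ruler") vals <- round_half_up(vals, params$ruler_rounding_mm)
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = seq_len(n), position_id = 1L,
          method = m, quantity = "incisor_width",
          value_mm = vals, true_mm = truth_width)
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$participant_id, out$position_id, out$quantity,
                     out$method), ]
    rownames(out) <- NULL
    out
  })
}
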