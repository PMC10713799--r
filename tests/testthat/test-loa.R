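test_that("independent limits of agreement follow hand arithmetic", {
  d <- paired_differences(1:3, rep(1, 3), c(-1, 0, 1))
  res <- loa_independent(d)
  expect_equal(res$mean_diff, 0)
  expect_equal(res$sd_total, 1)
  expect_equal(res$loa_lower, -1.96)
  expect_equal(res$loa_upper, 1.96)
  expect_equal(loa_span(res), 2 * 1.96)
  expect_error(loa_independent(paired_differences(1:2, c(1, 1), c(0, 1))))
})

test_that("one occasion per subject reduces repeated mode to independent", {
  set.seed(9)
  d <- paired_differences(1:20, rep(1, 20), rnorm(20, -0.5, 1.2))
  expect_warning(rep_res <- loa_repeated(d), "independent")
  ind_res <- loa_independent(d)
  expect_equal(rep_res$loa_lower, ind_res$loa_lower)
  expect_equal(rep_res$loa_upper, ind_res$loa_upper)
  expect_identical(rep_res$mode, "independent")
})

test_that("identical differences collapse the limits", {
  d <- paired_differences(rep(1:4, each = 2), rep(1:2, 4), rep(2.5, 8))
  res <- loa_repeated(d)
  expect_equal(res$mean_diff, 2.5)
  expect_equal(res$sd_total, 0)
  expect_equal(loa_span(res), 0)
})

test_that("LoA identities hold exactly for arbitrary inputs", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    occ <- sample(1:4, n, replace = TRUE)
    occ[1:2] <- 2
    d <- paired_differences(rep(seq_len(n), occ),
                            unlist(lapply(occ, seq_len)),
                            rnorm(sum(occ), runif(1, -3, 3), runif(1, 0.1, 2)))
    res <- loa_repeated(d)
    expect_equal(res$loa_lower, res$mean_diff - 1.96 * res$sd_total,
                 tolerance = 1e-12)
    expect_equal(res$loa_upper, res$mean_diff + 1.96 * res$sd_total,
                 tolerance = 1e-12)
    expect_equal(res$span, 2 * 1.96 * res$sd_total, tolerance = 1e-12)
    # truncation: total SD never drops below the within-subject floor
    expect_gte(res$sd_total + 1e-12, sqrt(res$sigma2_within))
  }
})

test_that("repeated-measures LoA recovers a known generating model", {
  # mean -0.91 and total SD 1.243 give limits near (-3.35, 1.52)
  set.seed(2024)
  sb <- 0.7
  sw <- sqrt(1.243^2 - 0.7^2)
  d <- simulate_differences(2000, 2, -0.91, sb, sw)
  res <- loa_repeated(d)
  expect_equal(res$mean_diff, -0.91, tolerance = 0.05)
  expect_equal(res$sd_total, 1.243, tolerance = 0.03)
  expect_equal(res$loa_lower, -3.35, tolerance = 0.12)
  expect_equal(res$loa_upper, 1.52, tolerance = 0.12)
  expect_equal(loa_span(res), 4.87, tolerance = 0.15)
})

test_that("negative between-subject variance estimates truncate to zero", {
  # within-subject spread dominates: raw (MSB - MSW) is often negative
  set.seed(5)
  hits <- 0
  for (i in 1:20) {
    d <- simulate_differences(6, 3, 0, sb = 0, sw = 2)
    res <- loa_repeated(d)
    expect_gte(res$sigma2_between, 0)
    expect_gte(res$sd_total, sqrt(res$sigma2_within) - 1e-12)
    if (res$sigma2_between == 0) hits <- hits + 1
  }
  expect_gt(hits, 0)
})

test_that("the planning factor and the fitted CI half-width agree", {
  set.seed(33)
  d <- simulate_differences(50, 2, -1, 0.6, 0.6)
  res <- loa_repeated(d)
  hw <- res$loa_upper_ci[2] - res$loa_upper
  expect_equal(hw, loa_ci_halfwidth_factor(100) * res$sd_total,
               tolerance = 1e-10)
})

test_that("differences use the gold-minus-comparator sign convention", {
  df <- data.frame(participant_id = c(1, 1), position_id = c(1, 1),
                   method = c("M1", "ruler"), quantity = "opening",
                   value_mm = c(30, 32))
  d <- differences_from_measurements(df, "M1", "ruler")
  expect_equal(d$diff_mm, -2)   # comparator overestimates -> negative
  expect_equal(d$mean_mm, 31)
})

test_that("Bland-Altman plots are written with the three guide lines", {
  set.seed(6)
  d <- simulate_differences(30, 2, -0.9, 0.6, 0.8)
  d$mean_mm <- rnorm(nrow(d), 25, 4)
  res <- loa_repeated(d)
  path <- withr::local_tempfile(fileext = ".png")
  p <- bland_altman_plot(d, res, out_path = path)
  expect_true(file.exists(path) && file.size(path) > 0)
  # the layers carry the mean line and both limits
  yint <- unlist(lapply(p$layers, function(l) l$data$yintercept))
  expect_setequal(round(yint, 6),
                  round(c(res$mean_diff, res$loa_lower, res$loa_upper), 6))
  expect_error(bland_altman_plot(d[0, ], res))
  expect_error(bland_altman_plot(d[, c("subject_id", "diff_mm")], res),
               "mean_mm")
})
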