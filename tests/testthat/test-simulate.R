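test_that("a perfect copy saturates strength at zero delay", {
  d <- simulate_dyad(duration_s = 30, coupling = 1, lag_frames = 0, seed = 5)
  res <- dyad_synchrony(d)
  expect_equal(res$strength, atanh(1 - 1e-12), tolerance = 1e-9)
  expect_equal(res$delay_s, 0)
})

test_that("simulated series are standardized, finite and of the right length", {
  d <- simulate_dyad(duration_s = 45, fs = 25, coupling = 0.5, lag_frames = 8,
                     seed = 6)
  for (s in list(d$participant, d$assessor)) {
    expect_length(s$values, 45 * 25)
    expect_true(all(is.finite(s$values)))
    expect_lt(abs(mean(s$values)), 1e-10)
    expect_lt(abs(sd(s$values) - 1), 1e-10)
  }
  expect_identical(
    simulate_dyad(duration_s = 30, coupling = 0.4, seed = 9)$participant$values,
    simulate_dyad(duration_s = 30, coupling = 0.4, seed = 9)$participant$values
  )
})

test_that("the follower role controls the sign of the measured delay", {
  dp <- simulate_dyad(duration_s = 60, coupling = 0.9, lag_frames = 10,
                      follower = "participant", seed = 7)
  expect_gt(dyad_synchrony(dp)$delay_s, 0)
  da <- simulate_dyad(duration_s = 60, coupling = 0.9, lag_frames = 10,
                      follower = "assessor", seed = 7)
  expect_lt(dyad_synchrony(da)$delay_s, 0)
})

test_that("invalid generator parameters are rejected", {
  expect_error(simulate_dyad(coupling = 1.2), class = "dyadsync_input_error")
  expect_error(simulate_dyad(duration_s = 10, lag_frames = 100),
               class = "dyadsync_input_error")
  expect_error(simulate_dyad(noise_ar1 = 1), class = "dyadsync_input_error")
})

test_that("cohorts have the requested design and ground-truth columns", {
  cs <- simulate_cohort(
    n_per_group = c(HC = 4, SUB = 5, CHR = 6), n_assessors = 5,
    duration_s = 30,
    calibration = calibrate_strength_map(duration_s = 30, reps = 2, seed = 1),
    seed = 2
  )
  expect_length(cs$dyads, 15L)
  expect_equal(as.integer(table(cs$truth$group)[c("HC", "SUB", "CHR")]),
               c(4L, 5L, 6L))
  expect_equal(length(unique(cs$truth$assessor_id)), 5L)
  expect_true(all(c("true_coupling", "true_lag_frames", "true_delay_s",
                    "assessor_intercept", "sips_n1", "gfs", "gfr") %in%
                    names(cs$truth)))
  expect_equal(cs$truth$dyad_type,
               paste0(cs$truth$assessor_sex, cs$truth$participant_sex))
  expect_true(all(cs$truth$true_coupling >= 0.02 &
                    cs$truth$true_coupling <= 0.98))
  # dyads carry the same metadata as the truth table
  expect_equal(vapply(cs$dyads, function(d) d$assessor_id, character(1)),
               cs$truth$assessor_id)
  expect_error(
    simulate_cohort(n_per_group = c(HC = 2, SUB = 2, CHR = 2),
                    n_assessors = 10, seed = 1),
    class = "dyadsync_input_error"
  )
})

test_that("zero assessor variance yields a near-zero fitted ICC", {
  cal <- calibrate_strength_map(duration_s = 30, reps = 3, seed = 3)
  iccs <- vapply(1:9, function(r) {
    cs <- simulate_cohort(
      n_per_group = c(HC = 20, SUB = 20, CHR = 20), n_assessors = 10,
      assessor_icc = 0, duration_s = 30, calibration = cal, seed = 100 + r
    )
    fit_strength_model(cohort_synchrony(cs), "strength")$icc
  }, numeric(1))
  expect_lt(median(iccs), 0.05)
})

test_that("estimated delay tracks the injected lag for strong coupling", {
  for (lag in c(-8, 3, 12)) {
    est <- vapply(1:5, function(s) {
      dyad_synchrony(simulate_dyad(duration_s = 60, coupling = 0.8,
                                   lag_frames = lag,
                                   seed = 200 + 10 * lag + s))$delay_s
    }, numeric(1))
    expect_lte(abs(median(est) - lag / 25), 1 / 25 + 1e-12)
  }
})

test_that("cohort keypoint export is read back to identical analyses", {
  cs <- simulate_cohort(
    n_per_group = c(HC = 1, SUB = 1, CHR = 1), n_assessors = 2,
    duration_s = 30,
    calibration = calibrate_strength_map(duration_s = 30, reps = 2, seed = 4),
    seed = 5
  )
  dir <- file.path(tempdir(), "cohort_export")
  write_cohort_keypoints(cs, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  files <- list.files(dir, pattern = "^D\\d+\\.csv$", full.names = TRUE)
  expect_length(files, 3L)
  d1 <- read_dyad(files[1], dyad_id = cs$truth$dyad_id[1])
  direct <- dyad_synchrony(cs$dyads[[1]])
  via_file <- dyad_synchrony(d1)
  expect_equal(via_file$strength, direct$strength, tolerance = 1e-8)
  expect_equal(via_file$delay_s, direct$delay_s)
})

test_that("cohort_synchrony returns one complete row per dyad", {
  cs <- simulate_cohort(
    n_per_group = c(HC = 2, SUB = 2, CHR = 2), n_assessors = 3,
    duration_s = 30,
    calibration = calibrate_strength_map(duration_s = 30, reps = 2, seed = 6),
    seed = 7
  )
  tab <- cohort_synchrony(cs, surrogates = surrogate_params(5, seed = 8))
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("strength", "delay_s", "total_movement", "pseudo_mean",
                    "pseudo_sd", "empirical_quantile", "true_coupling") %in%
                    names(tab)))
  expect_true(all(is.finite(tab$strength)))
  expect_true(all(tab$n_windows_valid > 0))
})
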