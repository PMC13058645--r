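# Synthetic dyads and cohorts with known ground truth.

# Standardized smoothed AR(1) noise: the stand-in for slow head-nod motion.
# phi controls the autocorrelation time (~1/(1-phi) frames), the short
# moving average removes frame-to-frame jitter.
smooth_ar1 <- function(n, phi, ma_frames) {
  innov <- rnorm(n + 4L * ma_frames) * sqrt(1 - phi^2)
  x <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                init = rnorm(1)))
  if (ma_frames > 1L) {
    x <- as.numeric(stats::filter(x, rep(1 / ma_frames, ma_frames), sides = 2))
  }
  x <- x[(2L * ma_frames + 1L):(2L * ma_frames + n)]
  (x - mean(x)) / sd(x)
}

#' Simulate one dyad with known coupling and lag
#'
#' Generates two aligned vertical-movement series emulating a recorded
#' interaction: the leader moves as standardized, smoothed AR(1) noise (slow,
#' autocorrelated motion resembling head nods), and the follower is a lagged
#' linear copy of the leader mixed with independent noise of the same
#' character:
#' `follower(t) = coupling * leader(t - lag) + sqrt(1 - coupling^2) * noise(t)`,
#' both series standardized. With the default `follower = "participant"`, a
#' positive `lag_frames` means the assessor's movement is ahead of the
#' participant's, so the measured delay of synchrony is expected at
#' `+lag_frames / fs` seconds; with `follower = "assessor"` the participant
#' leads and the expected delay is `-lag_frames / fs`.
#'
#' @param duration_s Recording length in seconds (default 600, i.e. the
#'   first 10 minutes of an interview at 25 Hz).
#' @param fs Frame rate (default 25).
#' @param coupling Linear coupling strength in `[0, 1]`; 0 gives two
#'   independent series, 1 a noiseless delayed copy.
#' @param lag_frames Signed lag of the follower behind the leader, in frames.
#' @param noise_ar1 AR(1) autocorrelation of the motion noise (default 0.95).
#' @param follower Which role follows (default `"participant"`).
#' @param ma_frames Moving-average smoothing width in frames (default 5,
#'   0.2 s at 25 Hz).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param dyad_id,group,participant_sex,assessor_sex,assessor_id Metadata
#'   passed to [dyad_recording()].
#' @return A [dyad_recording()] with unnormalized (raw-scale) series.
#' @examples
#' d <- simulate_dyad(duration_s = 60, coupling = 0.9, lag_frames = 10, seed = 1)
#' dyad_synchrony(d)   # delay close to +0.4 s
#' @export
simulate_dyad <- function(duration_s = 600, fs = 25, coupling = 0.5,
                          lag_frames = 0, noise_ar1 = 0.95,
                          follower = c("participant", "assessor"),
                          ma_frames = 5, seed = NULL,
                          dyad_id = "sim_dyad", group = "HC",
                          participant_sex = "F", assessor_sex = "F",
                          assessor_id = "sim_assessor") {
  follower <- match.arg(follower)
  check_scalar(duration_s, "duration_s", lower = 1)
  check_scalar(fs, "fs", lower = 1e-9)
  check_scalar(coupling, "coupling", lower = 0, upper = 1)
  check_scalar(lag_frames, "lag_frames", integerish = TRUE)
  check_scalar(noise_ar1, "noise_ar1", lower = 0, upper = 1 - 1e-9)
  check_scalar(ma_frames, "ma_frames", lower = 1, integerish = TRUE)
  n <- round(duration_s * fs)
  lag_frames <- as.integer(lag_frames)
  if (abs(lag_frames) >= n / 10) {
    stop_input("`lag_frames` must be below a tenth of the series length.")
  }
  pad <- abs(lag_frames)
  with_seed(seed, {
    ell <- smooth_ar1(n + 2L * pad, noise_ar1, as.integer(ma_frames))
    noise <- smooth_ar1(n + 2L * pad, noise_ar1, as.integer(ma_frames))
    t_idx <- seq_len(n) + pad
    leader <- ell[t_idx]
    follow <- coupling * ell[t_idx - lag_frames] +
      sqrt(1 - coupling^2) * noise[t_idx]
    leader <- (leader - mean(leader)) / sd(leader)
    follow <- (follow - mean(follow)) / sd(follow)
    if (follower == "participant") {
      p_vals <- follow; a_vals <- leader
    } else {
      p_vals <- leader; a_vals <- follow
    }
    dyad_recording(
      movement_series(p_vals, fs = fs, role = "participant"),
      movement_series(a_vals, fs = fs, role = "assessor"),
      dyad_id = dyad_id, group = group,
      participant_sex = participant_sex, assessor_sex = assessor_sex,
      assessor_id = assessor_id
    )
  })
}

#' Calibrate the coupling-to-strength response of the pipeline
#'
#' The cohort generator places assessor and dyad effects on the coupling
#' scale, but the intraclass correlation it must induce is defined on the
#' measured strength scale (Fisher-Z median peak correlation), a nonlinear,
#' noisy transform of coupling: below the chance peak floor the map is
#' nearly flat, above it roughly linear. This helper runs the full pipeline
#' over a coupling grid and returns the empirical response: a monotone
#' (isotonic) fit of mean strength against coupling plus the within-grid-
#' point SD of the strength estimate. [simulate_cohort()] propagates its
#' latent effects through this map to solve for the assessor-intercept SD
#' that induces a requested strength-scale ICC.
#'
#' @param duration_s,fs Dyad geometry matching the cohort to be generated.
#' @param params [wcc_params()] used for measurement.
#' @param couplings Grid of coupling values to probe.
#' @param reps Dyads per grid point.
#' @param noise_ar1,ma_frames Motion-noise parameters as in
#'   [simulate_dyad()].
#' @param seed Integer seed.
#' @return A list of class `strength_calibration`: `couplings`,
#'   `mean_strength` (isotonic fit), `raw_mean`, `sd_strength`
#'   (within-point SD of measured strength), and the geometry probed.
#' @export
calibrate_strength_map <- function(duration_s = 120, fs = 25,
                                   params = wcc_params(),
                                   couplings = seq(0.05, 0.95, by = 0.05),
                                   reps = 8, noise_ar1 = 0.95, ma_frames = 5,
                                   seed = NULL) {
  with_seed(seed, {
    strengths <- vapply(couplings, function(cp) {
      vapply(seq_len(reps), function(r) {
        d <- simulate_dyad(duration_s = duration_s, fs = fs, coupling = cp,
                           lag_frames = 0, noise_ar1 = noise_ar1,
                           ma_frames = ma_frames)
        dyad_synchrony(d, params)$strength
      }, numeric(1))
    }, numeric(reps))
    raw_mean <- colMeans(strengths)
    structure(
      list(
        couplings = couplings,
        mean_strength = stats::isoreg(couplings, raw_mean)$yf,
        raw_mean = raw_mean,
        sd_strength = apply(strengths, 2, sd),
        reps = reps, duration_s = duration_s, fs = fs
      ),
      class = "strength_calibration"
    )
  })
}

# Interpolators over the calibrated response.
cal_mean <- function(cal, coupling) {
  approx(cal$couplings, cal$mean_strength, xout = coupling, rule = 2)$y
}
cal_sd <- function(cal, coupling) {
  approx(cal$couplings, cal$sd_strength, xout = coupling, rule = 2)$y
}

# Strength-scale ICC induced by assessor-intercept SD `sd_u` on the coupling
# scale, computed by common-random-numbers Monte Carlo through the
# calibrated map. Group-weighted variance decomposition: assessor component
# = variance over assessor intercepts of the expected strength; residual =
# dyad-coupling variation through the map plus measurement noise.
induced_strength_icc <- function(sd_u, cal, group_means, group_n,
                                 coupling_sd, n_u = 1000, n_e = 120) {
  zu <- stats::qnorm(seq_len(n_u) / (n_u + 1))
  ze <- stats::qnorm(seq_len(n_e) / (n_e + 1))
  w <- group_n / sum(group_n)
  A <- 0; R <- 0
  for (gi in seq_along(group_means)) {
    cmat <- pmin(pmax(group_means[gi] + outer(sd_u * zu, coupling_sd * ze, "+"),
                      0.02), 0.98)
    smat <- matrix(cal_mean(cal, cmat), nrow = n_u)
    h_u <- rowMeans(smat)
    var_e <- rowMeans(smat^2) - h_u^2
    sm2 <- mean(cal_sd(cal, cmat)^2)
    A <- A + w[gi] * var(h_u) * (n_u - 1) / n_u
    R <- R + w[gi] * (mean(var_e) + sm2)
  }
  A / (A + R)
}

# Solve for the assessor-intercept SD achieving the target strength ICC.
solve_assessor_sd <- function(cal, target_icc, group_means, group_n,
                              coupling_sd) {
  if (target_icc <= 0) return(0)
  f <- function(su) {
    induced_strength_icc(su, cal, group_means, group_n, coupling_sd) -
      target_icc
  }
  upper <- 0.5
  if (f(upper) < 0) return(upper)  # saturating map: best attainable
  stats::uniroot(f, c(0, upper), tol = 1e-4)$root
}

#' Simulate a full cohort with group effects and assessor nesting
#'
#' Generates dyads for a three-group cohort (healthy controls, sub-threshold
#' help-seekers, clinical high risk) nested in a pool of assessors, with
#' known ground truth for every latent quantity. Each dyad's coupling is
#' `group mean + assessor intercept + dyad deviation` (clamped to
#' `[0.02, 0.98]`); the assessor-intercept SD is solved from the requested
#' ICC of measured strength by propagating the latent effects through the
#' empirical coupling-to-strength response of a [calibrate_strength_map()]
#' run (supplied or computed on the fly). Lags are drawn per dyad, sexes
#' are balanced Bernoulli draws, and synthetic symptom / functioning scores
#' are linear functions of the true delay and coupling plus noise, so
#' downstream correlation code paths are exercised with known sign
#' structure.
#'
#' @param n_per_group Named counts for groups `HC`, `SUB`, `CHR` (defaults
#'   30 / 36 / 50).
#' @param n_assessors Number of assessors dyads are nested in (default 32).
#' @param assessor_icc Target proportion of measured-strength variance
#'   attributable to assessors (default 0.141).
#' @param group_coupling_means Named mean couplings per group. The defaults
#'   (HC 0.65, SUB 0.62, CHR 0.57) sit in the responsive region of the
#'   coupling-to-strength map and encode a CHR deficit sized to produce a
#'   mean strength difference of about -0.05 Fisher-Z versus HC.
#' @param coupling_sd Dyad-level SD of coupling around its group/assessor
#'   mean (default 0.08).
#' @param lag_sd_frames SD of the per-dyad true lag draw (frames, rounded to
#'   integers; default 5).
#' @param duration_s,fs,noise_ar1,ma_frames Dyad geometry; see
#'   [simulate_dyad()]. The default cohort duration is 120 s, long enough
#'   for stable per-dyad medians while keeping cohort-scale simulation
#'   studies fast.
#' @param calibration A `strength_calibration` for this geometry, or `NULL`
#'   to compute one (seeded from `seed`). Pass a precomputed object when
#'   generating many cohorts of identical geometry.
#' @param seed Integer seed.
#' @return A list of class `cohort_sim`: `dyads` (list of
#'   [dyad_recording()]) and `truth`, a tibble with one row per dyad holding
#'   design columns (`dyad_id`, `group`, `assessor_id`, sexes, `dyad_type`)
#'   and ground-truth columns (`true_coupling`, `true_lag_frames`,
#'   `true_delay_s`, `assessor_intercept`) plus synthetic scores `sips_n1`
#'   (social anhedonia stand-in), `gfs`, `gfr` (social/role functioning
#'   stand-ins).
#' @export
simulate_cohort <- function(n_per_group = c(HC = 30, SUB = 36, CHR = 50),
                            n_assessors = 32, assessor_icc = 0.141,
                            group_coupling_means = c(HC = 0.65, SUB = 0.62,
                                                     CHR = 0.57),
                            coupling_sd = 0.08, lag_sd_frames = 5,
                            duration_s = 120, fs = 25, noise_ar1 = 0.95,
                            ma_frames = 5, calibration = NULL, seed = NULL) {
  groups <- c("HC", "SUB", "CHR")
  if (!all(groups %in% names(n_per_group)) ||
      !all(groups %in% names(group_coupling_means))) {
    stop_input("`n_per_group` and `group_coupling_means` must name HC, SUB, CHR.")
  }
  check_scalar(assessor_icc, "assessor_icc", lower = 0, upper = 1 - 1e-9)
  n_total <- sum(n_per_group[groups])
  check_scalar(n_assessors, "n_assessors", lower = 1, integerish = TRUE)
  if (n_assessors > n_total) {
    stop_input("`n_assessors` cannot exceed the number of dyads.")
  }
  if (is.null(calibration)) {
    calibration <- calibrate_strength_map(
      duration_s = duration_s, fs = fs, noise_ar1 = noise_ar1,
      ma_frames = ma_frames,
      seed = if (is.null(seed)) NULL else seed + 1L
    )
  }
  sd_u <- solve_assessor_sd(calibration, assessor_icc,
                            group_coupling_means[groups],
                            n_per_group[groups], coupling_sd)

  with_seed(seed, {
    group <- factor(rep(groups, times = n_per_group[groups]), levels = groups)
    assessor_id <- sample(rep_len(sprintf("A%02d", seq_len(n_assessors)),
                                  n_total))
    u <- setNames(rnorm(n_assessors, sd = sd_u),
                  sprintf("A%02d", seq_len(n_assessors)))
    true_coupling <- pmin(pmax(
      group_coupling_means[as.character(group)] + u[assessor_id] +
        rnorm(n_total, sd = coupling_sd), 0.02), 0.98)
    true_lag <- as.integer(round(rnorm(n_total, sd = lag_sd_frames)))
    participant_sex <- sample(c("F", "M"), n_total, replace = TRUE)
    assessor_sex <- sample(c("F", "M"), n_total, replace = TRUE)
    true_delay_s <- true_lag / fs
    # synthetic score models (slopes are arbitrary but sign-true stand-ins):
    # social anhedonia rises with following delay; functioning with coupling
    n1_base <- c(HC = 0.5, SUB = 2.5, CHR = 3.5)
    sips_n1 <- n1_base[as.character(group)] + 2.0 * true_delay_s +
      rnorm(n_total, sd = 1)
    gfs_base <- c(HC = 8.5, SUB = 7.0, CHR = 6.5)
    gfs <- gfs_base[as.character(group)] + 3.0 * true_coupling +
      rnorm(n_total, sd = 1)
    gfr <- gfs_base[as.character(group)] + 2.5 * true_coupling +
      rnorm(n_total, sd = 1)
    dyad_id <- sprintf("D%03d", seq_len(n_total))
    truth <- tibble(
      dyad_id = dyad_id, group = group, assessor_id = assessor_id,
      participant_sex = participant_sex, assessor_sex = assessor_sex,
      dyad_type = paste0(assessor_sex, participant_sex),
      true_coupling = unname(true_coupling),
      true_lag_frames = true_lag, true_delay_s = true_delay_s,
      assessor_intercept = unname(u[assessor_id]),
      sips_n1 = unname(sips_n1), gfs = unname(gfs), gfr = unname(gfr)
    )
    dyads <- purrr::pmap(
      list(dyad_id, as.character(group), true_coupling, true_lag,
           participant_sex, assessor_sex, assessor_id),
      function(id, g, cpl, lag, psex, asex, aid) {
        simulate_dyad(
          duration_s = duration_s, fs = fs, coupling = cpl,
          lag_frames = lag, noise_ar1 = noise_ar1, ma_frames = ma_frames,
          dyad_id = id, group = g, participant_sex = psex,
          assessor_sex = asex, assessor_id = aid
        )
      }
    )
    structure(list(dyads = dyads, truth = truth, calibration = calibration),
              class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d dyads (%s) nested in %d assessors\n",
    length(x$dyads),
    paste(sprintf("%s=%d", names(table(x$truth$group)),
                  as.integer(table(x$truth$group))), collapse = ", "),
    length(unique(x$truth$assessor_id))
  ))
  invisible(x)
}

#' Convert a simulated dyad to pose-tracker keypoint format
#'
#' Renders a dyad's two series as a keypoint table of the kind a pose
#' tracker exports for a side-by-side two-tile recording: the participant's
#' nose near the left tile center, the assessor's near the right, vertical
#' position carrying the movement. Lets the reading/role-assignment path be
#' exercised on synthetic data.
#'
#' @param dyad A [dyad_recording()].
#' @param participant_x,assessor_x Horizontal tile centers in pixels.
#' @param y_center,y_scale Mapping from (standardized) movement values to
#'   pixel y coordinates.
#' @return A `keypoint_table` tibble with persons `"P1"` (left, participant)
#'   and `"P2"` (right, assessor), landmark 0.
#' @export
as_keypoint_table <- function(dyad, participant_x = 160, assessor_x = 480,
                              y_center = 240, y_scale = 40) {
  n <- length(dyad$participant$values)
  out <- tibble(
    frame_index = rep(seq_len(n) - 1L, 2L),
    person_id = rep(c("P1", "P2"), each = n),
    landmark_id = 0L,
    x = rep(c(participant_x, assessor_x), each = n),
    y = y_center + y_scale * c(dyad$participant$values, dyad$assessor$values)
  )
  class(out) <- c("keypoint_table", class(out))
  out
}

#' Write a simulated cohort as keypoint files plus ground truth
#'
#' One keypoint CSV per dyad (via [as_keypoint_table()]) and a
#' `ground_truth.csv` with the cohort's truth table, so a full analysis can
#' be driven from files exactly as with real tracker exports.
#'
#' @param cohort A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_keypoints <- function(cohort, dir) {
  if (!inherits(cohort, "cohort_sim")) {
    stop_input("`cohort` must come from simulate_cohort().")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in cohort$dyads) {
    write_keypoints(as_keypoint_table(d),
                    file.path(dir, paste0(d$dyad_id, ".csv")))
  }
  readr::write_csv(cohort$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
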