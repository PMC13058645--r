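test_that("Fisher Z matches its closed form, is odd, and clips near |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.82), 1.1568, tolerance = 1e-4)
  expect_equal(fisher_z(-0.5), -0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(r), fisher_hand(r), tolerance = 1e-12)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_message(z1 <- fisher_z(1), "Clipped")
  expect_equal(z1, atanh(1 - 1e-12))
  expect_true(is.finite(fisher_z(-1, quiet = TRUE)))
})

test_that("lagged correlation follows the assessor-leads sign convention", {
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(200), 0.9, method = "recursive"))
  expect_equal(lagged_correlation(x, x, 0), 1.0)

  # participant(t) = assessor(t - 5): perfect correlation at lag +5
  a <- as.numeric(stats::filter(rnorm(205), 0.9, method = "recursive"))
  participant <- a[1:200]
  assessor <- a[6:205]
  # the assessor runs 5 frames ahead of the participant
  expect_equal(lagged_correlation(participant, assessor, 5), 1.0,
               tolerance = 1e-12)

  wn1 <- rnorm(100); wn2 <- rnorm(100)
  expect_equal(lagged_correlation(wn1, wn2, 0), pearson_hand(wn1, wn2),
               tolerance = 1e-12)
  expect_equal(lagged_correlation(wn1, wn2, 7),
               pearson_hand(wn1[8:100], wn2[1:93]), tolerance = 1e-12)

  expect_true(is.na(lagged_correlation(rep(1, 50), rnorm(50), 0)))
  expect_error(lagged_correlation(1:10, 1:9, 0),
               class = "dyadsync_input_error")
  expect_error(lagged_correlation(1:10, 1:10, 8),
               class = "dyadsync_input_error")
})

make_dyad <- function(p, a, fs = 25) {
  dyad_recording(
    movement_series(p, fs = fs, role = "participant"),
    movement_series(a, fs = fs, role = "assessor")
  )
}

test_that("wcc has the documented geometry and flags degenerate windows", {
  set.seed(10)
  v <- as.numeric(stats::filter(rnorm(600), 0.9, method = "recursive"))
  d <- make_dyad(v, v)
  res <- wcc(d)
  expect_equal(ncol(res$z_matrix), 2L * 50L + 1L)
  expect_equal(nrow(res$z_matrix), (600 - 90) %/% 45 + 1L)
  expect_equal(res$lags, -50:50)
  # identical series: every window peaks at lag 0, at the clip ceiling
  pk <- pick_peaks(res)
  expect_true(all(pk$peak_lag_frames == 0L))
  expect_true(all(abs(pk$peak_z - atanh(1 - 1e-12)) < 1e-9))

  short <- make_dyad(rnorm(100), rnorm(100))
  expect_error(wcc(short), class = "dyadsync_input_error")

  # constant participant: all windows invalid
  dc <- make_dyad(rep(1, 600), v)
  expect_warning(pkc <- pick_peaks(wcc(dc)), "invalid")
  expect_true(all(!pkc$valid))
})

test_that("wcc matches the naive triple-loop oracle cell by cell", {
  set.seed(20)
  for (i in 1:5) {
    p <- as.numeric(stats::filter(rnorm(600), 0.8, method = "recursive"))
    a <- as.numeric(stats::filter(rnorm(600), 0.8, method = "recursive"))
    d <- make_dyad(p, a)
    prm <- wcc_params(window_frames = 60, overlap_frames = 30,
                      max_lag_frames = 20)
    res <- wcc(d, prm)
    ref <- naive_wcc(p, a, 60, 30, 20)
    expect_equal(unname(res$z_matrix), ref, tolerance = 1e-10)
  }
})

test_that("peak picking takes the signed maximum with the stated tie rules", {
  lags <- -5:5
  mk <- function(zrow) {
    structure(
      list(z_matrix = matrix(zrow, nrow = 1,
                             dimnames = list(NULL, as.character(lags))),
           lags = lags, window_starts = 0L, fs = 25,
           params = wcc_params(window_frames = 30, overlap_frames = 15,
                               max_lag_frames = 5),
           dyad_id = "t", n_clipped = 0L),
      class = "wcc_result"
    )
  }
  # parabola peaking at lag -3
  pk <- pick_peaks(mk(-(lags + 3)^2))
  expect_equal(pk$peak_lag_frames, -3L)
  expect_false(pk$boundary)
  # flat row: tie resolved to lag 0
  pk0 <- pick_peaks(mk(rep(0.4, 11)))
  expect_equal(pk0$peak_lag_frames, 0L)
  # symmetric tie at +/-2: negative preferred
  z <- rep(0, 11); z[lags == 2] <- 0.9; z[lags == -2] <- 0.9
  expect_equal(pick_peaks(mk(z))$peak_lag_frames, -2L)
  # boundary maximum flagged but retained
  zb <- seq(0, 1, length.out = 11)
  pkb <- pick_peaks(mk(zb))
  expect_equal(pkb$peak_lag_frames, 5L)
  expect_true(pkb$boundary)
})

test_that("peak picking equals an exhaustive scan on random matrices", {
  set.seed(30)
  lags <- -10:10
  prm <- wcc_params(window_frames = 40, overlap_frames = 20,
                    max_lag_frames = 10)
  for (i in 1:10) {
    z <- matrix(rnorm(15 * 21), 15, 21)
    res <- structure(
      list(z_matrix = z, lags = lags,
           window_starts = seq(0L, by = 20L, length.out = 15L), fs = 25,
           params = prm, dyad_id = "t", n_clipped = 0L),
      class = "wcc_result"
    )
    pk <- pick_peaks(res)
    ref <- naive_peaks(z, lags)
    expect_equal(pk$peak_z, ref[, 1])
    expect_equal(pk$peak_lag_frames, as.integer(ref[, 2]))
  }
})

test_that("summaries use median conventions and report delay in seconds", {
  prm <- wcc_params()
  mk_peaks <- function(z, lag) {
    out <- tibble::tibble(
      window = seq_along(z), window_start = 0L, peak_z = z,
      peak_lag_frames = as.integer(lag), valid = TRUE, boundary = FALSE
    )
    attr(out, "params") <- prm
    attr(out, "fs") <- 25
    class(out) <- c("peak_series", class(out))
    out
  }
  s1 <- summarize_synchrony(mk_peaks(c(1.0, 1.2, 1.4), c(-5, 0, 5)))
  expect_equal(s1$strength, 1.2)
  expect_equal(s1$delay_s, 0)
  s2 <- summarize_synchrony(mk_peaks(c(1.0, 1.2), c(2, 4)))
  expect_equal(s2$strength, 1.1)
  expect_equal(s2$delay_s, 0.12)  # midpoint median 3 frames / 25 Hz
})

test_that("a lagged copy plus noise is summarized at the injected delay", {
  est <- vapply(1:5, function(s) {
    d <- simulate_dyad(duration_s = 60, coupling = 0.9, lag_frames = 10,
                       seed = 40 + s)
    dyad_synchrony(d)$delay_s
  }, numeric(1))
  expect_true(all(abs(est - 0.40) <= 0.04 + 1e-12))
})

test_that("swapping participant and assessor negates delay, keeps strength", {
  for (s in 1:5) {
    d <- simulate_dyad(duration_s = 60, coupling = 0.8, lag_frames = 7,
                       seed = 50 + s)
    swapped <- make_dyad(d$assessor$values, d$participant$values)
    a <- dyad_synchrony(d)
    b <- dyad_synchrony(swapped)
    expect_equal(a$strength, b$strength, tolerance = 1e-10)
    expect_equal(a$delay_s, -b$delay_s, tolerance = 1e-10)
  }
})

test_that("5 s and 7 s windows rank dyads consistently with 3.6 s windows", {
  set.seed(60)
  couplings <- runif(15, 0.1, 0.95)
  dyads <- lapply(seq_along(couplings), function(i) {
    preprocess_dyad(simulate_dyad(duration_s = 60, coupling = couplings[i],
                                  lag_frames = sample(-8:8, 1)))
  })
  strength_for <- function(win) {
    prm <- wcc_params(window_frames = win, overlap_frames = win %/% 2)
    vapply(dyads, function(d) {
      summarize_synchrony(pick_peaks(wcc(d, prm)))$strength
    }, numeric(1))
  }
  s36 <- strength_for(90)
  expect_gt(cor(s36, strength_for(125), method = "spearman"), 0.8)
  expect_gt(cor(s36, strength_for(175), method = "spearman"), 0.8)
})

test_that("independent noise never increases mean strength at fixed seeds", {
  couplings <- c(0, 0.25, 0.5, 0.75, 0.9)
  means <- vapply(couplings, function(cp) {
    mean(vapply(1:60, function(s) {
      dyad_synchrony(simulate_dyad(duration_s = 60, coupling = cp,
                                   seed = 70 + s))$strength
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("wcc results expose tidy, glance and heat-map views", {
  d <- simulate_dyad(duration_s = 30, coupling = 0.7, lag_frames = 4, seed = 81)
  res <- wcc(preprocess_dyad(d))
  td <- tidy(res)
  expect_equal(nrow(td), nrow(res$z_matrix) * length(res$lags))
  expect_named(td, c("window", "window_start", "time_s", "lag_frames",
                     "lag_s", "z"))
  gl <- glance(res)
  expect_equal(gl$window_s, 3.6)
  expect_equal(gl$max_lag_s, 2)
  expect_s3_class(autoplot(res, show_peaks = TRUE), "ggplot")
})

test_that("noiseless shifted copies recover every lag below the search bound", {
  for (L in seq(-49, 49, by = 7)) {
    d <- simulate_dyad(duration_s = 30, coupling = 1, lag_frames = L,
                       seed = 300)
    expect_equal(dyad_synchrony(d)$delay_s, L / 25)
  }
})
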