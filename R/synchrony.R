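#' Windowed cross-correlation parameters
#'
#' Defaults follow the standard head-nod configuration at 25 Hz: 90-frame
#' (3.6 s) windows with 50% overlap (45 frames) and lags up to 50 frames
#' (2 s) in both directions. Alternative window widths (e.g. 5 s = 125
#' frames, 7 s = 175 frames) are supported for sensitivity analyses.
#'
#' @param window_frames Window width in frames.
#' @param overlap_frames Overlap between consecutive windows, in frames;
#'   must satisfy `0 < overlap_frames < window_frames`.
#' @param max_lag_frames Maximum lag examined in each direction, in frames.
#' @param fs Sampling rate in frames per second.
#' @return A list of class `wcc_params`.
#' @examples
#' wcc_params()                      # 3.6 s windows
#' wcc_params(window_frames = 125)   # 5 s windows at 25 Hz
#' @export
wcc_params <- function(window_frames = 90, overlap_frames = 45,
                       max_lag_frames = 50, fs = 25) {
  check_scalar(window_frames, "window_frames", lower = 4, integerish = TRUE)
  check_scalar(overlap_frames, "overlap_frames", lower = 1, integerish = TRUE)
  check_scalar(max_lag_frames, "max_lag_frames", lower = 1, integerish = TRUE)
  check_scalar(fs, "fs", lower = 1e-9)
  if (overlap_frames >= window_frames) {
    stop_input("`overlap_frames` must be smaller than `window_frames`.")
  }
  if (window_frames - max_lag_frames < 3) {
    stop_input("`max_lag_frames` leaves fewer than 3 overlapping points per window.")
  }
  structure(
    list(window_frames = as.integer(window_frames),
         overlap_frames = as.integer(overlap_frames),
         max_lag_frames = as.integer(max_lag_frames),
         fs = as.numeric(fs)),
    class = "wcc_params"
  )
}

#' Fisher Z transform
#'
#' The variance-stabilizing transform `artanh(r)` applied to correlation
#' coefficients before peak picking and medians; values exceed 1 once the
#' correlation passes tanh(1), about 0.76. Correlations within `1e-12` of
#' +/-1 are clipped to
#' `+/-(1 - 1e-12)` (and counted via a message) so the transform stays finite.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @param quiet Suppress the clipping message.
#' @return `atanh` of the (possibly clipped) input; an odd, strictly
#'   increasing function.
#' @examples
#' fisher_z(c(0, 0.5, 0.82))
#' @export
fisher_z <- function(r, quiet = FALSE) {
  clip <- 1 - 1e-12
  n_clipped <- sum(abs(r) >= clip, na.rm = TRUE)
  if (n_clipped > 0L && !quiet) {
    inform(sprintf("Clipped %d correlation(s) at |r| = 1 - 1e-12.", n_clipped))
  }
  atanh(pmin(pmax(r, -clip), clip))
}

#' Lagged Pearson correlation of two equal-length segments
#'
#' Correlates the participant's values at time t with the assessor's values
#' at time t - lag over the overlapping range, so a positive lag means the
#' assessor's movement is ahead of (leads) the participant's.
#'
#' @param a Participant segment (numeric).
#' @param b Assessor segment, same length.
#' @param lag Signed lag in frames; `|lag|` must leave at least 3
#'   overlapping points.
#' @return The Pearson correlation, or `NA` when either overlapping segment
#'   has zero variance (correlation undefined there, not an error).
#' @examples
#' x <- sin(seq(0, 10, by = 0.1))
#' lagged_correlation(x, x, lag = 0)
#' @export
lagged_correlation <- function(a, b, lag = 0) {
  if (length(a) != length(b)) stop_input("Segments must have equal length.")
  check_scalar(lag, "lag", integerish = TRUE)
  lag <- as.integer(lag)
  n <- length(a)
  if (n - abs(lag) < 3L) {
    stop_input("Overlap after shifting must be at least 3 points.")
  }
  if (lag >= 0L) {
    x <- a[(1L + lag):n]
    y <- b[1L:(n - lag)]
  } else {
    x <- a[1L:(n + lag)]
    y <- b[(1L - lag):n]
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Windowed cross-correlation of a dyad
#'
#' Splits the two (preprocessed) series into overlapping windows and, within
#' each window, computes the lagged Pearson correlation at every lag from
#' `-max_lag_frames` to `+max_lag_frames`, Fisher-Z transformed. Trailing
#' partial windows are dropped. Window/lag cells where either shifted
#' segment has zero variance are `NA` (invalid).
#'
#' @param dyad A [dyad_recording()] whose series are preprocessed and of
#'   equal length at least `window_frames + max_lag_frames`.
#' @param params A [wcc_params()] object; its `fs` is overridden by the
#'   dyad's frame rate if they differ.
#' @return An object of class `wcc_result`: list with `z_matrix` (windows x
#'   lags, Fisher-Z units), `lags` (frames), `window_starts` (0-based
#'   frames), `fs`, `params` and the dyad's id.
#' @seealso [pick_peaks()], [summarize_synchrony()], [dyad_synchrony()]
#' @export
wcc <- function(dyad, params = wcc_params()) {
  if (!inherits(dyad, "dyad_recording")) {
    stop_input("`dyad` must be a dyad_recording.")
  }
  if (!inherits(params, "wcc_params")) {
    stop_input("`params` must come from wcc_params().")
  }
  p <- dyad$participant$values
  a <- dyad$assessor$values
  n <- length(p)
  if (n < params$window_frames + params$max_lag_frames) {
    stop_input(sprintf(
      "Series length %d is shorter than window + max_lag = %d frames.",
      n, params$window_frames + params$max_lag_frames
    ))
  }
  stride <- params$window_frames - params$overlap_frames
  r <- .wcc_core(p, a, params$window_frames, stride, params$max_lag_frames)
  z <- fisher_z(r, quiet = TRUE)
  n_clipped <- sum(abs(r) >= 1 - 1e-12, na.rm = TRUE)
  lags <- seq(-params$max_lag_frames, params$max_lag_frames)
  dimnames(z) <- list(NULL, as.character(lags))
  structure(
    list(
      z_matrix = z,
      lags = lags,
      window_starts = (seq_len(nrow(z)) - 1L) * stride,
      fs = dyad$participant$fs,
      params = params,
      dyad_id = dyad$dyad_id,
      n_clipped = n_clipped
    ),
    class = "wcc_result"
  )
}

#' @export
print.wcc_result <- function(x, ...) {
  cat(sprintf(
    "<wcc_result> %s: %d windows x %d lags (+/-%.2f s) at %g Hz\n",
    x$dyad_id, nrow(x$z_matrix), length(x$lags),
    max(x$lags) / x$fs, x$fs
  ))
  invisible(x)
}

#' Per-window peak picking on a WCC matrix
#'
#' For each window, selects the lag with the maximum signed Fisher-Z
#' cross-correlation (in-phase coordination scores high; out-of-phase does
#' not). Exact ties are broken toward the smallest absolute lag, then toward
#' the negative lag. Windows whose maximum sits on a lag boundary are kept
#' but flagged `boundary`; windows with no finite cell are invalid.
#'
#' @param result A `wcc_result` from [wcc()].
#' @return A tibble of class `peak_series` with one row per window:
#'   `window`, `window_start`, `peak_z`, `peak_lag_frames`, `valid`,
#'   `boundary`; carries the `wcc_params` and `fs` as attributes.
#' @export
pick_peaks <- function(result) {
  if (!inherits(result, "wcc_result")) {
    stop_input("`result` must be a wcc_result.")
  }
  z <- result$z_matrix
  lags <- result$lags
  max_lag <- max(lags)
  # candidate order implementing the tie rule: smallest |lag| first,
  # negative before positive at equal |lag|
  ord <- order(abs(lags), lags)
  n_win <- nrow(z)
  peak_z <- rep(NA_real_, n_win)
  peak_lag <- rep(NA_integer_, n_win)
  valid <- rep(FALSE, n_win)
  for (wi in seq_len(n_win)) {
    row <- z[wi, ]
    if (all(is.na(row))) next
    m <- max(row, na.rm = TRUE)
    best <- ord[which(row[ord] == m)[1]]
    peak_z[wi] <- m
    peak_lag[wi] <- lags[best]
    valid[wi] <- TRUE
  }
  if (!any(valid)) {
    warn("All windows are invalid (zero variance everywhere); empty peak series.")
  }
  out <- tibble(
    window = seq_len(n_win),
    window_start = result$window_starts,
    peak_z = peak_z,
    peak_lag_frames = peak_lag,
    valid = valid,
    boundary = valid & abs(peak_lag) == max_lag
  )
  attr(out, "params") <- result$params
  attr(out, "fs") <- result$fs
  attr(out, "dyad_id") <- result$dyad_id
  class(out) <- c("peak_series", class(out))
  out
}

#' Summarize peak series to per-dyad strength and delay of synchrony
#'
#' Strength is the median, over valid windows, of the peak Fisher-Z
#' cross-correlation; delay is the median peak lag converted to seconds,
#' signed so that a positive delay means the assessor's movement precedes
#' the participant's (the participant follows). Even-count medians use the
#' midpoint convention.
#'
#' @param peaks A `peak_series` from [pick_peaks()].
#' @param params Optional [wcc_params()]; defaults to the parameters carried
#'   by `peaks`.
#' @return A one-row tibble of class `synchrony_result` with columns
#'   `dyad_id`, `strength` (Fisher-Z units), `delay_s` (seconds, signed) and
#'   `n_windows_valid`. If no window is valid, `strength` and `delay_s` are
#'   `NA` (dyad-level missing result).
#' @export
summarize_synchrony <- function(peaks, params = attr(peaks, "params")) {
  if (!inherits(peaks, "peak_series")) {
    stop_input("`peaks` must be a peak_series.")
  }
  fs <- attr(peaks, "fs") %||% params$fs
  ok <- peaks$valid
  n_valid <- sum(ok)
  tibble(
    dyad_id = attr(peaks, "dyad_id") %||% NA_character_,
    strength = if (n_valid > 0L) median(peaks$peak_z[ok]) else NA_real_,
    delay_s = if (n_valid > 0L) median(peaks$peak_lag_frames[ok]) / fs else NA_real_,
    n_windows_valid = n_valid
  ) |>
    structure(class = c("synchrony_result", class(tibble())))
}

#' One-call synchrony analysis of a dyad
#'
#' Convenience chain: optional preprocessing, [wcc()], [pick_peaks()],
#' [summarize_synchrony()].
#'
#' @param dyad A [dyad_recording()].
#' @param params A [wcc_params()] object.
#' @param preprocess Apply [preprocess_dyad()] first (default `TRUE`; set
#'   `FALSE` if the series are already cleaned and normalized).
#' @param preprocess_params Parameters for the preprocessing stage.
#' @return A one-row `synchrony_result` tibble (see
#'   [summarize_synchrony()]).
#' @examples
#' d <- simulate_dyad(duration_s = 30, coupling = 0.8, lag_frames = 5, seed = 1)
#' dyad_synchrony(d)
#' @export
dyad_synchrony <- function(dyad, params = wcc_params(), preprocess = TRUE,
                           preprocess_params = dyadsync::preprocess_params()) {
  if (preprocess) dyad <- preprocess_dyad(dyad, preprocess_params)
  summarize_synchrony(pick_peaks(wcc(dyad, params)))
}
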