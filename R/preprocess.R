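#' Preprocessing parameters
#'
#' Bundles the cleaning parameters applied to each raw trajectory before
#' synchrony analysis: the scaled-MAD outlier multiplier, the median-filter
#' order, and whether to z-normalize. The defaults (`mad_k = 3`,
#' `median_filter_order = 15` frames, normalization on) are the standard
#' settings for 25 Hz head-nod series. An even filter order is incremented to
#' the next odd value with a message, since a centered window needs an odd
#' width.
#'
#' @param mad_k Scaled-MAD multiplier for outlier detection; points further
#'   than `mad_k` scaled MADs from the median are flagged.
#' @param median_filter_order Width (frames) of the centered median filter.
#' @param normalize Z-normalize (center, scale to unit SD) the cleaned series.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(mad_k = 3, median_filter_order = 15,
                              normalize = TRUE) {
  check_scalar(mad_k, "mad_k", lower = 1e-12)
  check_scalar(median_filter_order, "median_filter_order", lower = 1,
               integerish = TRUE)
  median_filter_order <- as.integer(median_filter_order)
  if (median_filter_order %% 2L == 0L) {
    inform(sprintf(
      "median_filter_order %d is even; using %d (centered windows need odd width).",
      median_filter_order, median_filter_order + 1L
    ))
    median_filter_order <- median_filter_order + 1L
  }
  structure(
    list(mad_k = mad_k, median_filter_order = median_filter_order,
         normalize = isTRUE(normalize)),
    class = "preprocess_params"
  )
}

#' Flag outliers by the scaled-MAD rule
#'
#' A point is an outlier when its absolute deviation from the median exceeds
#' `k` scaled median absolute deviations, where the scaled MAD is
#' `1.4826 * median(|x - median(x)|)` (the consistency constant for normal
#' data). When the MAD is zero (at least half the values identical) nothing is
#' flagged: the robust spread estimate carries no information there.
#'
#' @param values Numeric vector, length at least 3. `NA`s are never flagged.
#' @param k Multiplier (default 3).
#' @return Logical mask, `TRUE` at outliers.
#' @examples
#' detect_outliers_mad(c(1, 2, 3, 4, 100))
#' @export
detect_outliers_mad <- function(values, k = 3) {
  if (length(values) < 3L) stop_input("Need at least 3 values.")
  check_scalar(k, "k", lower = 1e-12)
  med <- median(values, na.rm = TRUE)
  dev <- abs(values - med)
  mad_raw <- median(dev, na.rm = TRUE)
  if (!is.finite(mad_raw) || mad_raw == 0) {
    return(rep(FALSE, length(values)))
  }
  mask <- dev > k * 1.4826 * mad_raw
  mask[is.na(mask)] <- FALSE
  mask
}

#' Fill missing points by linear interpolation
#'
#' Interior gaps are linearly interpolated between the nearest valid
#' neighbours; leading and trailing gaps are filled with the nearest valid
#' value (constant extrapolation), so no trend is invented beyond the data.
#'
#' @param values Numeric vector with `NA` at missing points.
#' @return Complete numeric vector of the same length.
#' @examples
#' interpolate_linear(c(1, NA, 3))
#' interpolate_linear(c(NA, 2, 4))
#' @export
interpolate_linear <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    stop_input("Need at least 2 non-missing points to interpolate.")
  }
  if (all(ok)) return(values)
  idx <- seq_along(values)
  approx(idx[ok], values[ok], xout = idx, method = "linear", rule = 2)$y
}

#' Centered running-median filter
#'
#' Sliding median of odd width `order`, centered on each point. Near the
#' boundaries the window is truncated to the available samples (no padding
#' values are invented), so the first point's window is the first
#' `(order + 1) / 2` samples.
#'
#' @param values Complete numeric vector.
#' @param order Odd window width in frames, at most `length(values)`.
#' @return Filtered vector of the same length.
#' @export
median_filter <- function(values, order = 15) {
  check_scalar(order, "order", lower = 1, integerish = TRUE)
  order <- as.integer(order)
  if (order %% 2L == 0L) stop_input("`order` must be odd.")
  n <- length(values)
  if (order > n) stop_input("`order` exceeds series length.")
  if (order == 1L) return(values)
  h <- (order - 1L) %/% 2L
  out <- as.numeric(runmed(values, order, endrule = "keep"))
  # truncated (not shrunken-symmetric) windows at the boundaries
  edge <- seq_len(min(h, n))
  for (i in edge) out[i] <- median(values[1:min(n, i + h)])
  for (i in (n - edge + 1L)) out[i] <- median(values[max(1L, i - h):n])
  out
}

#' Z-normalize a series
#'
#' Centers to mean zero and rescales to unit standard deviation (sample SD,
#' denominator n - 1). A constant series cannot be normalized and raises a
#' degenerate-series error; such dyads are excluded upstream.
#'
#' @param values Complete numeric vector with positive SD.
#' @return Normalized vector: mean 0 and SD 1 to within 1e-8.
#' @export
znormalize <- function(values) {
  s <- sd(values)
  if (!is.finite(s) || s <= 0) {
    abort("Constant (zero-variance) series cannot be normalized.",
          class = "dyadsync_degenerate_error")
  }
  (values - mean(values)) / s
}

#' Total amount of movement
#'
#' Summarizes how much a person moved over the recording. `abs_position`
#' (default) sums absolute position values at every timepoint, computed on
#' the normalized series; `abs_displacement` sums absolute frame-to-frame
#' displacements (path length), offered because the position-sum reading is
#' ambiguous for centered series.
#'
#' @param values Complete numeric vector.
#' @param mode `"abs_position"` or `"abs_displacement"`.
#' @return A single non-negative number.
#' @examples
#' total_movement(c(1, -1, 1, -1))
#' total_movement(c(0, 1, 0, 1), mode = "abs_displacement")
#' @export
total_movement <- function(values, mode = c("abs_position", "abs_displacement")) {
  mode <- match.arg(mode)
  if (anyNA(values)) stop_input("`values` must be complete (no NA).")
  if (mode == "abs_position") sum(abs(values)) else sum(abs(diff(values)))
}

#' Preprocess a movement series
#'
#' Applies the cleaning chain in its fixed order: scaled-MAD outlier removal,
#' linear interpolation of removed/missing points, centered median filtering,
#' then z-normalization. The returned series carries a `preprocess_log`
#' attribute with the number of missing frames filled and outliers removed.
#'
#' @param series A [movement_series()] (may contain `NA` at missing frames).
#' @param params A [preprocess_params()] object.
#' @return A cleaned `movement_series` with `normalized = TRUE` (when
#'   normalization is enabled).
#' @export
preprocess_series <- function(series, params = preprocess_params()) {
  if (!inherits(series, "movement_series")) {
    stop_input("`series` must be a movement_series.")
  }
  if (!inherits(params, "preprocess_params")) {
    stop_input("`params` must come from preprocess_params().")
  }
  v <- series$values
  n_missing <- sum(is.na(v))
  mask <- detect_outliers_mad(v, k = params$mad_k)
  v[mask] <- NA_real_
  if (anyNA(v)) v <- interpolate_linear(v)
  v <- median_filter(v, order = params$median_filter_order)
  if (params$normalize) v <- znormalize(v)
  out <- movement_series(v, fs = series$fs, role = series$role,
                         axis = series$axis, landmark_id = series$landmark_id,
                         normalized = params$normalize)
  attr(out, "preprocess_log") <- list(
    n_missing_filled = n_missing,
    n_outliers_removed = sum(mask)
  )
  out
}

#' Preprocess both series of a dyad
#'
#' @param dyad A [dyad_recording()].
#' @param params A [preprocess_params()] object.
#' @return The dyad with both series cleaned.
#' @export
preprocess_dyad <- function(dyad, params = preprocess_params()) {
  if (!inherits(dyad, "dyad_recording")) {
    stop_input("`dyad` must be a dyad_recording.")
  }
  dyad$participant <- preprocess_series(dyad$participant, params)
  dyad$assessor <- preprocess_series(dyad$assessor, params)
  dyad
}
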