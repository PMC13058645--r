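# ggplot2 views of the package's result objects.

#' Lag-versus-time heat map of a windowed cross-correlation
#'
#' The classic WCC visual: window time on the x axis, lag (seconds, signed;
#' positive = assessor leads) on the y axis, Fisher-Z cross-correlation as
#' fill. Peak lags per window can be overlaid.
#'
#' @param object A `wcc_result` from [wcc()].
#' @param show_peaks Overlay the per-window peak lags.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wcc_result <- function(object, show_peaks = FALSE, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$lag_s,
                                        fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "Fisher Z") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(
      x = "Time (s)", y = "Lag (s; + = assessor leads)",
      title = sprintf("Windowed cross-correlation: %s", object$dyad_id)
    ) +
    ggplot2::theme_minimal()
  if (show_peaks) {
    pk <- pick_peaks(object)
    pk <- pk[pk$valid, , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = tibble(
        time_s = (pk$window_start + object$params$window_frames / 2) /
          object$fs,
        lag_s = pk$peak_lag_frames / object$fs
      ),
      ggplot2::aes(x = .data$time_s, y = .data$lag_s),
      inherit.aes = FALSE, size = 0.6
    )
  }
  p
}

#' Histogram of a pseudosynchrony null with the genuine value marked
#'
#' @param object A `surrogate_null` from [pseudosynchrony()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surrogate_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$strength)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$genuine_strength,
                        colour = "#b2182b", linewidth = 0.8) +
    ggplot2::labs(
      x = "Strength of synchrony (Fisher Z)", y = "Surrogates",
      title = sprintf("Pseudosynchrony null: %s", object$dyad_id),
      subtitle = sprintf("genuine = %.3f, pseudo mean = %.3f",
                         object$genuine_strength, object$pseudo_strength)
    ) +
    ggplot2::theme_minimal()
}

#' Strength of synchrony by group across a cohort
#'
#' Box plots of per-dyad strength by cohort group, with dyads jittered.
#'
#' @param cohort A cohort tibble from [cohort_synchrony()].
#' @param outcome Column to display (default `"strength"`).
#' @return A ggplot object.
#' @export
plot_cohort_synchrony <- function(cohort, outcome = "strength") {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$group,
                                       y = .data[[outcome]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = outcome) +
    ggplot2::theme_minimal()
}
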