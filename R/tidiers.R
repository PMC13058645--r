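# broom-style tidiers for the package's result objects.

#' Tidy a windowed cross-correlation result
#'
#' @param x A `wcc_result` from [wcc()].
#' @param ... Unused.
#' @return A long tibble with one row per window x lag cell: `window`,
#'   `window_start`, `time_s` (window center), `lag_frames`, `lag_s`, `z`.
#' @export
tidy.wcc_result <- function(x, ...) {
  n_win <- nrow(x$z_matrix)
  tibble(
    window = rep(seq_len(n_win), times = length(x$lags)),
    window_start = rep(x$window_starts, times = length(x$lags)),
    time_s = rep((x$window_starts + x$params$window_frames / 2) / x$fs,
                 times = length(x$lags)),
    lag_frames = rep(x$lags, each = n_win),
    lag_s = rep(x$lags / x$fs, each = n_win),
    z = as.vector(x$z_matrix)
  )
}

#' Glance at a windowed cross-correlation result
#'
#' @param x A `wcc_result`.
#' @param ... Unused.
#' @return One-row tibble with the summarized strength and delay plus
#'   configuration facts.
#' @export
glance.wcc_result <- function(x, ...) {
  res <- summarize_synchrony(pick_peaks(x))
  tibble(
    dyad_id = res$dyad_id, strength = res$strength, delay_s = res$delay_s,
    n_windows = nrow(x$z_matrix), n_windows_valid = res$n_windows_valid,
    window_s = x$params$window_frames / x$fs,
    max_lag_s = x$params$max_lag_frames / x$fs
  )
}

#' Tidy a surrogate null
#'
#' @param x A `surrogate_null` from [pseudosynchrony()].
#' @param ... Unused.
#' @return Tibble with one row per surrogate: `surrogate`, `strength`.
#' @export
tidy.surrogate_null <- function(x, ...) {
  tibble(surrogate = seq_along(x$strengths), strength = x$strengths)
}

#' Glance at a surrogate null
#'
#' @param x A `surrogate_null`.
#' @param ... Unused.
#' @return One-row tibble: genuine strength, pseudo mean/SD, empirical
#'   quantile of the genuine value in the null, surrogate count.
#' @export
glance.surrogate_null <- function(x, ...) {
  tibble(
    dyad_id = x$dyad_id,
    genuine_strength = x$genuine_strength,
    pseudo_mean = x$pseudo_strength,
    pseudo_sd = sd(x$strengths),
    empirical_quantile = x$empirical_quantile_of_genuine,
    n_surrogates = length(x$strengths)
  )
}

#' Tidy an assessor-nested mixed model
#'
#' @param x A `synchrony_mixed_model` from [fit_strength_model()].
#' @param effects `"fixed"` (default) or `"ran_pars"` for the variance
#'   components.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates with Wald 95% confidence limits
#'   and Satterthwaite p values, or of variance components.
#' @export
tidy.synchrony_mixed_model <- function(x, effects = c("fixed", "ran_pars"),
                                       ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") return(x$fixed)
  tibble(
    term = c("var_assessor", "var_residual"),
    estimate = c(x$var_assessor, x$var_residual)
  )
}

#' Glance at an assessor-nested mixed model
#'
#' @param x A `synchrony_mixed_model`.
#' @param ... Unused.
#' @return One-row tibble: `icc`, variance components, group sizes,
#'   `singular`, REML criterion.
#' @export
glance.synchrony_mixed_model <- function(x, ...) {
  tibble(
    outcome = x$outcome, icc = x$icc,
    var_assessor = x$var_assessor, var_residual = x$var_residual,
    n = x$n, n_assessors = x$n_assessors,
    singular = x$singular,
    REMLcrit = stats::deviance(x$fit, REML = TRUE)
  )
}
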