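#' Run the full synchrony pipeline over a cohort of dyads
#'
#' Preprocesses every dyad, computes per-dyad strength and delay of
#' synchrony and total movement, and (optionally) the segment-shuffle
#' pseudosynchrony null. Dyads whose series are degenerate (constant after
#' cleaning) are excluded with a warning rather than failing the cohort.
#'
#' @param dyads A list of [dyad_recording()] objects, or a `cohort_sim` from
#'   [simulate_cohort()] (whose truth table is then joined onto the result).
#' @param params A [wcc_params()] object.
#' @param preprocess_params A [preprocess_params()] object.
#' @param surrogates A [surrogate_params()] object to add pseudosynchrony
#'   columns, or `NULL` (default) to skip the null.
#' @param movement_mode Mode for [total_movement()] on the participant's
#'   cleaned series.
#' @return A tibble (the cohort table) with one row per dyad: `dyad_id`,
#'   `group`, `participant_sex`, `assessor_sex`, `dyad_type`, `assessor_id`,
#'   `strength`, `delay_s`, `n_windows_valid`, `total_movement`,
#'   `total_movement_assessor`, and — when `surrogates` is given —
#'   `pseudo_mean`, `pseudo_sd`, `empirical_quantile`. For a `cohort_sim`
#'   input, ground-truth and score columns are appended.
#' @examples
#' cs <- simulate_cohort(n_per_group = c(HC = 3, SUB = 3, CHR = 3),
#'                       n_assessors = 3, duration_s = 30, seed = 1)
#' cohort_synchrony(cs)
#' @export
cohort_synchrony <- function(dyads, params = wcc_params(),
                             preprocess_params = dyadsync::preprocess_params(),
                             surrogates = NULL,
                             movement_mode = "abs_position") {
  truth <- NULL
  if (inherits(dyads, "cohort_sim")) {
    truth <- dyads$truth
    dyads <- dyads$dyads
  }
  rows <- purrr::imap(dyads, function(d, i) {
    clean <- tryCatch(preprocess_dyad(d, preprocess_params),
                      dyadsync_degenerate_error = function(e) NULL)
    if (is.null(clean)) {
      warn(sprintf("Dyad %s excluded: degenerate series.", d$dyad_id))
      return(NULL)
    }
    res <- summarize_synchrony(pick_peaks(wcc(clean, params)))
    row <- tibble(
      dyad_id = d$dyad_id, group = d$group,
      participant_sex = d$participant_sex, assessor_sex = d$assessor_sex,
      dyad_type = paste0(d$assessor_sex, d$participant_sex),
      assessor_id = d$assessor_id,
      strength = res$strength, delay_s = res$delay_s,
      n_windows_valid = res$n_windows_valid,
      total_movement = total_movement(clean$participant$values,
                                      mode = movement_mode),
      total_movement_assessor = total_movement(clean$assessor$values,
                                               mode = movement_mode)
    )
    if (!is.null(surrogates)) {
      surr_i <- surrogates
      # distinct, reproducible surrogate stream per dyad
      if (!is.null(surr_i$seed)) surr_i$seed <- surr_i$seed + i
      null <- pseudosynchrony(clean, params, surr_i)
      row$pseudo_mean <- null$pseudo_strength
      row$pseudo_sd <- sd(null$strengths)
      row$empirical_quantile <- null$empirical_quantile_of_genuine
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(truth)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(truth, -dplyr::any_of(c(
        "group", "participant_sex", "assessor_sex", "dyad_type", "assessor_id"
      ))),
      by = "dyad_id"
    )
  }
  out
}
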