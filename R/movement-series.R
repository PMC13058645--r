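#' Movement series and dyad recording containers
#'
#' A `movement_series` holds one person's one-dimensional landmark trajectory
#' (by default the vertical nose position, the signal carrying head nods)
#' together with its sampling rate and provenance. A `dyad_recording` pairs
#' the participant's and assessor's aligned series with dyad metadata.
#'
#' @param values Numeric vector of positions (pixels, or dimensionless after
#'   normalization). `NA` marks frames to be filled by interpolation.
#' @param fs Sampling rate in frames per second.
#' @param role `"participant"` or `"assessor"`.
#' @param axis `"x"` or `"y"`; vertical (`"y"`) is the head-nod axis.
#' @param landmark_id Non-negative integer landmark index (nose is 0 in
#'   17-keypoint pose models).
#' @param normalized Logical; `TRUE` once the series has been z-normalized.
#'
#' @return `movement_series()` returns an object of class `movement_series`;
#'   `dyad_recording()` returns an object of class `dyad_recording`.
#' @examples
#' s <- movement_series(sin(seq(0, 20, by = 0.04)), fs = 25)
#' s
#' as_tibble(s)
#' @export
movement_series <- function(values, fs = 25, role = c("participant", "assessor"),
                            axis = c("y", "x"), landmark_id = 0L,
                            normalized = FALSE) {
  role <- match.arg(role)
  axis <- match.arg(axis)
  if (!is.numeric(values) || length(values) == 0L) {
    stop_input("`values` must be a non-empty numeric vector.")
  }
  check_scalar(fs, "fs", lower = 1e-9)
  check_scalar(landmark_id, "landmark_id", lower = 0, integerish = TRUE)
  structure(
    list(
      values = as.numeric(values),
      fs = as.numeric(fs),
      role = role,
      axis = axis,
      landmark_id = as.integer(landmark_id),
      normalized = isTRUE(normalized)
    ),
    class = "movement_series"
  )
}

#' @rdname movement_series
#' @param participant,assessor `movement_series` objects sharing `fs` and
#'   length, with distinct roles.
#' @param dyad_id,assessor_id Opaque identifier labels.
#' @param group Cohort group: `"HC"` (healthy control), `"SUB"` (sub-threshold
#'   help-seeking control) or `"CHR"` (clinical high risk).
#' @param participant_sex,assessor_sex `"M"` or `"F"`.
#' @export
dyad_recording <- function(participant, assessor, dyad_id = "dyad",
                           group = c("HC", "SUB", "CHR"),
                           participant_sex = c("F", "M"),
                           assessor_sex = c("F", "M"),
                           assessor_id = "assessor") {
  group <- match.arg(group)
  participant_sex <- match.arg(participant_sex)
  assessor_sex <- match.arg(assessor_sex)
  if (!inherits(participant, "movement_series") ||
      !inherits(assessor, "movement_series")) {
    stop_input("`participant` and `assessor` must be movement_series objects.")
  }
  if (identical(participant$role, assessor$role)) {
    stop_input("The two series of a dyad must have distinct roles.")
  }
  if (length(participant$values) != length(assessor$values)) {
    stop_input("Participant and assessor series must have equal length.")
  }
  if (!isTRUE(all.equal(participant$fs, assessor$fs))) {
    stop_input("Participant and assessor series must share the same frame rate.")
  }
  structure(
    list(
      participant = participant,
      assessor = assessor,
      dyad_id = as.character(dyad_id),
      group = group,
      participant_sex = participant_sex,
      assessor_sex = assessor_sex,
      assessor_id = as.character(assessor_id)
    ),
    class = "dyad_recording"
  )
}

#' @export
print.movement_series <- function(x, ...) {
  cat(sprintf(
    "<movement_series> %s, %s-axis, landmark %d: %d frames at %g Hz (%.1f s)%s\n",
    x$role, x$axis, x$landmark_id, length(x$values), x$fs,
    length(x$values) / x$fs,
    if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf(
    "<dyad_recording> %s [%s]: %d frames at %g Hz, assessor %s (%s/%s)\n",
    x$dyad_id, x$group, length(x$participant$values), x$participant$fs,
    x$assessor_id, x$participant_sex, x$assessor_sex
  ))
  invisible(x)
}

#' @export
as_tibble.movement_series <- function(x, ...) {
  n <- length(x$values)
  tibble(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / x$fs,
    value = x$values
  )
}

#' @export
as_tibble.dyad_recording <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(as_tibble(x$participant), role = "participant"),
    dplyr::mutate(as_tibble(x$assessor), role = "assessor")
  )
}

#' Write a movement series to a two-column CSV
#'
#' Serializes a series as `frame,value` rows for inspection or interchange.
#'
#' @param series A `movement_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "movement_series")) {
    stop_input("`series` must be a movement_series.")
  }
  readr::write_csv(as_tibble(series)[, c("frame", "value")], path)
  invisible(path)
}
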