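#' Column-name dialect for pose-tracker keypoint exports
#'
#' Pose trackers export per-frame keypoint tables under varying column names.
#' A dialect maps the exporter's names onto the canonical columns
#' `frame_index`, `person_id`, `landmark_id`, `x`, `y` and (optionally)
#' `confidence`. The default dialect matches a generic per-frame keypoint CSV.
#'
#' @param frame_index,person_id,landmark_id,x,y,confidence Column names in the
#'   source file. `confidence` may be `NA` if the file has no score column.
#' @param delim Field delimiter; `","` for CSV, `"\t"` for TSV.
#' @return A named list of class `keypoint_dialect`.
#' @examples
#' keypoint_dialect()
#' keypoint_dialect(frame_index = "frame_id", confidence = NA)
#' @export
keypoint_dialect <- function(frame_index = "frame", person_id = "person",
                             landmark_id = "landmark", x = "x", y = "y",
                             confidence = "conf", delim = ",") {
  structure(
    list(frame_index = frame_index, person_id = person_id,
         landmark_id = landmark_id, x = x, y = y,
         confidence = confidence, delim = delim),
    class = "keypoint_dialect"
  )
}

#' Read a pose-tracker keypoint table
#'
#' Reads a delimited text export (or JSON-lines with the same fields) of
#' per-frame 2D keypoints for the two people in a recording, renames columns
#' per the dialect, drops rows with unparseable coordinates (counting them in
#' the `n_dropped` attribute), and validates the result: coordinates numeric,
#' at most one row per (frame, person, landmark), and at least two distinct
#' persons present.
#'
#' @param path Path to a CSV/TSV file, or a `.jsonl`/`.ndjson` JSON-lines file.
#' @param dialect A [keypoint_dialect()] mapping source column names.
#' @return A tibble of class `keypoint_table` with columns `frame_index`,
#'   `person_id`, `landmark_id`, `x`, `y` and optionally `confidence`, plus an
#'   attribute `n_dropped` counting discarded malformed rows.
#' @seealso [extract_series()], [assign_roles()], [write_keypoints()]
#' @export
read_keypoints <- function(path, dialect = keypoint_dialect()) {
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    raw <- as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  } else {
    raw <- readr::read_delim(
      path, delim = dialect$delim, show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  needed <- c("frame_index", "person_id", "landmark_id", "x", "y")
  src <- unlist(dialect[needed])
  missing_cols <- setdiff(src, names(raw))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf(
      "Missing required column(s): %s (dialect expects %s).",
      paste(missing_cols, collapse = ", "), paste(src, collapse = ", ")
    ))
  }
  out <- tibble(
    frame_index = suppressWarnings(as.integer(raw[[dialect$frame_index]])),
    person_id = as.character(raw[[dialect$person_id]]),
    landmark_id = suppressWarnings(as.integer(raw[[dialect$landmark_id]])),
    x = suppressWarnings(as.numeric(raw[[dialect$x]])),
    y = suppressWarnings(as.numeric(raw[[dialect$y]]))
  )
  if (!is.na(dialect$confidence) && dialect$confidence %in% names(raw)) {
    out$confidence <- suppressWarnings(as.numeric(raw[[dialect$confidence]]))
  }
  bad <- !complete.cases(out[, needed])
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    inform(sprintf("Dropped %d row(s) with unparseable fields.", n_dropped))
    out <- out[!bad, , drop = FALSE]
  }
  validate_keypoint_table(out)
  out <- dplyr::arrange(out, .data$person_id, .data$landmark_id,
                        .data$frame_index)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("keypoint_table", class(out))
  out
}

validate_keypoint_table <- function(tab) {
  if (nrow(tab) == 0L) stop_input("Keypoint table is empty.")
  if (any(tab$frame_index < 0L) || any(tab$landmark_id < 0L)) {
    stop_format("frame_index and landmark_id must be non-negative.")
  }
  dup <- duplicated(tab[, c("frame_index", "person_id", "landmark_id")])
  if (any(dup)) {
    stop_format(sprintf(
      "%d duplicated (frame, person, landmark) row(s).", sum(dup)
    ))
  }
  n_persons <- length(unique(tab$person_id))
  if (n_persons < 2L) {
    stop_input(sprintf(
      "Expected two persons in the recording, found %d.", n_persons
    ))
  }
  invisible(tab)
}

#' Write a keypoint table back to delimited text
#'
#' Inverse of [read_keypoints()] for the built-in dialect; round-trips values
#' exactly (coordinates are written with full precision).
#'
#' @param table A `keypoint_table` (or compatible data frame).
#' @param path Output path.
#' @param dialect Dialect giving the output column names and delimiter.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(table, path, dialect = keypoint_dialect()) {
  out <- tibble(
    a = table$frame_index, b = table$person_id, c = table$landmark_id,
    d = table$x, e = table$y
  )
  names(out) <- unlist(dialect[c("frame_index", "person_id", "landmark_id",
                                 "x", "y")])
  if ("confidence" %in% names(table) && !is.na(dialect$confidence)) {
    out[[dialect$confidence]] <- table$confidence
  }
  readr::write_delim(out, path, delim = dialect$delim)
  invisible(path)
}

#' Extract one person's landmark trajectory as a movement series
#'
#' Selects one coordinate axis of one landmark for one person and orders it by
#' frame over the recording's full frame range (taken across both persons so
#' the two extracted series align). Frames without a row for that person are
#' marked `NA`, to be filled by the preprocessing interpolation step.
#'
#' @param table A `keypoint_table` from [read_keypoints()].
#' @param person_id Person label to extract.
#' @param landmark_id Landmark index (default 0, the nose).
#' @param axis `"y"` (vertical, head nods; default) or `"x"`.
#' @param fs Sampling rate in frames per second (default 25).
#' @param role Role to stamp on the series.
#' @return A [movement_series()] whose values may contain `NA` at missing
#'   frames.
#' @export
extract_series <- function(table, person_id, landmark_id = 0L,
                           axis = c("y", "x"), fs = 25,
                           role = c("participant", "assessor")) {
  axis <- match.arg(axis)
  role <- match.arg(role)
  sel <- table[table$person_id == person_id &
                 table$landmark_id == landmark_id, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop_input(sprintf(
      "No rows for person '%s', landmark %d.", person_id, landmark_id
    ))
  }
  frames <- seq(min(table$frame_index), max(table$frame_index))
  values <- rep(NA_real_, length(frames))
  values[match(sel$frame_index, frames)] <- sel[[axis]]
  movement_series(values, fs = fs, role = role, axis = axis,
                  landmark_id = landmark_id)
}

#' Assign participant and assessor roles to the two tracked persons
#'
#' Recordings show the two faces side by side; which tile holds the
#' participant is a property of the recording setup, so the assignment is
#' explicit configuration, never silently inferred. The `leftmost_is` rule
#' assigns the given role to the person with the smaller median x coordinate.
#'
#' @param table A `keypoint_table` containing exactly two persons.
#' @param rule `"leftmost_is"` (default) or `"explicit"`.
#' @param leftmost Role of the left tile under `rule = "leftmost_is"`.
#' @param map Named character vector `c(person_id = role, ...)` for
#'   `rule = "explicit"`.
#' @return A named character vector mapping each `person_id` to
#'   `"participant"` or `"assessor"`.
#' @export
assign_roles <- function(table, rule = c("leftmost_is", "explicit"),
                         leftmost = c("participant", "assessor"),
                         map = NULL) {
  rule <- match.arg(rule)
  leftmost <- match.arg(leftmost)
  persons <- sort(unique(table$person_id))
  if (length(persons) != 2L) {
    stop_input(sprintf("Role assignment needs exactly 2 persons, found %d.",
                       length(persons)))
  }
  roles <- c("participant", "assessor")
  if (rule == "explicit") {
    if (is.null(map) || !setequal(names(map), persons) ||
        !setequal(unname(map), roles)) {
      stop_input("`map` must name both persons and both roles exactly once.")
    }
    return(map[persons])
  }
  med_x <- vapply(persons, function(p) {
    median(table$x[table$person_id == p], na.rm = TRUE)
  }, numeric(1))
  if (isTRUE(all.equal(med_x[[1]], med_x[[2]]))) {
    abort(paste0(
      "Median x positions are tied; cannot infer tiles. ",
      "Use rule = \"explicit\" with a role map."
    ), class = "dyadsync_tie_error")
  }
  left <- persons[which.min(med_x)]
  right <- setdiff(persons, left)
  other <- setdiff(roles, leftmost)
  setNames(c(leftmost, other), c(left, right))[persons]
}

#' Read a keypoint file directly into a dyad recording
#'
#' Convenience wrapper: [read_keypoints()], [assign_roles()], then
#' [extract_series()] for both persons on the chosen landmark/axis.
#'
#' @inheritParams read_keypoints
#' @inheritParams extract_series
#' @inheritParams assign_roles
#' @inheritParams dyad_recording
#' @return A [dyad_recording()].
#' @export
read_dyad <- function(path, dialect = keypoint_dialect(), landmark_id = 0L,
                      axis = "y", fs = 25, rule = "leftmost_is",
                      leftmost = "participant", map = NULL,
                      dyad_id = "dyad", group = "HC",
                      participant_sex = "F", assessor_sex = "F",
                      assessor_id = "assessor") {
  tab <- read_keypoints(path, dialect = dialect)
  roles <- assign_roles(tab, rule = rule, leftmost = leftmost, map = map)
  series <- lapply(names(roles), function(p) {
    extract_series(tab, p, landmark_id = landmark_id, axis = axis, fs = fs,
                   role = roles[[p]])
  })
  names(series) <- unname(roles)
  dyad_recording(series$participant, series$assessor, dyad_id = dyad_id,
                 group = group, participant_sex = participant_sex,
                 assessor_sex = assessor_sex, assessor_id = assessor_id)
}
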