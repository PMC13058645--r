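#' Surrogate (pseudosynchrony) parameters
#'
#' Controls the segment-shuffle null: how many surrogate datasets to build,
#' the shuffled segment length (defaulting to the WCC window width so each
#' segment spans one analysis window), and which partner's series is
#' shuffled. Shuffling one partner is enough to destroy the temporal
#' alignment between the two; shuffling both is available for sensitivity
#' analyses.
#'
#' @param n_surrogates Number of surrogate datasets (default 100).
#' @param segment_frames Segment length in frames; `NULL` (default) means
#'   "use the WCC window width".
#' @param shuffle_target `"participant"` (default), `"assessor"` or
#'   `"both"`.
#' @param seed Integer seed making the null bit-reproducible; `NULL` uses
#'   the current RNG stream.
#' @return A list of class `surrogate_params`.
#' @export
surrogate_params <- function(n_surrogates = 100, segment_frames = NULL,
                             shuffle_target = c("participant", "assessor", "both"),
                             seed = NULL) {
  shuffle_target <- match.arg(shuffle_target)
  check_scalar(n_surrogates, "n_surrogates", lower = 1, integerish = TRUE)
  if (!is.null(segment_frames)) {
    check_scalar(segment_frames, "segment_frames", lower = 2, integerish = TRUE)
    segment_frames <- as.integer(segment_frames)
  }
  structure(
    list(n_surrogates = as.integer(n_surrogates),
         segment_frames = segment_frames,
         shuffle_target = shuffle_target,
         seed = seed),
    class = "surrogate_params"
  )
}

#' Shuffle a series in consecutive segments
#'
#' Partitions the series into consecutive non-overlapping segments of
#' `segment_frames` frames and permutes the segment order uniformly at
#' random. A shorter final remainder stays in place at the end. Length and
#' the multiset of values are preserved exactly; only the temporal
#' arrangement across segments is destroyed.
#'
#' @param values Numeric vector of length at least `2 * segment_frames`.
#' @param segment_frames Segment length in frames.
#' @param perm Optional explicit permutation of the full segments (for
#'   reproducing a specific shuffle); `NULL` draws one uniformly.
#' @return Shuffled vector of the same length.
#' @examples
#' segment_shuffle(1:6, 3, perm = c(2, 1))
#' @export
segment_shuffle <- function(values, segment_frames, perm = NULL) {
  check_scalar(segment_frames, "segment_frames", lower = 2, integerish = TRUE)
  segment_frames <- as.integer(segment_frames)
  n <- length(values)
  n_seg <- n %/% segment_frames
  if (n_seg < 2L) {
    stop_input("Need at least 2 full segments to shuffle.")
  }
  if (is.null(perm)) {
    perm <- sample.int(n_seg)
  } else if (!setequal(perm, seq_len(n_seg))) {
    stop_input(sprintf("`perm` must be a permutation of 1..%d.", n_seg))
  }
  head_len <- n_seg * segment_frames
  idx <- as.vector(vapply(perm, function(s) {
    ((s - 1L) * segment_frames + 1L):(s * segment_frames)
  }, integer(segment_frames)))
  c(values[idx], if (head_len < n) values[(head_len + 1L):n])
}

#' Pseudosynchrony null for one dyad
#'
#' Builds the chance-level reference for a dyad's synchrony: the chosen
#' partner's (preprocessed) series is segment-shuffled `n_surrogates` times
#' and the full strength computation (WCC, Fisher Z, peak picking, median)
#' is repeated on each surrogate pair. Individual movement structure within
#' segments is preserved; the interpersonal alignment is destroyed.
#'
#' @param dyad A preprocessed [dyad_recording()] (see [preprocess_dyad()]).
#' @param params A [wcc_params()] object.
#' @param surr A [surrogate_params()] object.
#' @return An object of class `surrogate_null`: list with `strengths`
#'   (vector of surrogate strengths, Fisher-Z units), `pseudo_strength`
#'   (their mean), `pseudo_median`, `genuine_strength`, and
#'   `empirical_quantile_of_genuine` (fraction of surrogates weaker than the
#'   genuine strength).
#' @examples
#' d <- preprocess_dyad(simulate_dyad(duration_s = 30, coupling = 0.9, seed = 1))
#' pseudosynchrony(d, surr = surrogate_params(n_surrogates = 5, seed = 1))
#' @export
pseudosynchrony <- function(dyad, params = wcc_params(),
                            surr = surrogate_params()) {
  if (!inherits(dyad, "dyad_recording")) {
    stop_input("`dyad` must be a dyad_recording.")
  }
  seg <- surr$segment_frames %||% params$window_frames
  genuine <- summarize_synchrony(pick_peaks(wcc(dyad, params)))$strength
  strengths <- with_seed(surr$seed, {
    vapply(seq_len(surr$n_surrogates), function(i) {
      sdyad <- dyad
      if (surr$shuffle_target %in% c("participant", "both")) {
        sdyad$participant$values <-
          segment_shuffle(sdyad$participant$values, seg)
      }
      if (surr$shuffle_target %in% c("assessor", "both")) {
        sdyad$assessor$values <- segment_shuffle(sdyad$assessor$values, seg)
      }
      summarize_synchrony(pick_peaks(wcc(sdyad, params)))$strength
    }, numeric(1))
  })
  structure(
    list(
      dyad_id = dyad$dyad_id,
      strengths = strengths,
      pseudo_strength = mean(strengths),
      pseudo_median = median(strengths),
      genuine_strength = genuine,
      empirical_quantile_of_genuine = mean(strengths < genuine),
      params = params,
      surrogate_params = surr
    ),
    class = "surrogate_null"
  )
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf(
    "<surrogate_null> %s: genuine %.3f vs pseudo %.3f +/- %.3f (n = %d, quantile %.2f)\n",
    x$dyad_id, x$genuine_strength, x$pseudo_strength, sd(x$strengths),
    length(x$strengths), x$empirical_quantile_of_genuine
  ))
  invisible(x)
}

#' Paired test of genuine versus pseudosynchrony across a cohort
#'
#' Dependent (paired) t-test of each dyad's genuine strength against its own
#' pseudosynchrony summary — the check that measured synchrony exceeds what
#' segment-shuffled chance produces.
#'
#' @param cohort Data frame with one row per dyad.
#' @param genuine,pseudo Names of the genuine and pseudo strength columns.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_genuine`, `sd_genuine`,
#'   `mean_pseudo`, `sd_pseudo`, `mean_diff`, `n`, `degenerate`. A constant
#'   nonzero difference has infinite t and is flagged `degenerate`; all-equal
#'   pairs give `t = 0`, `p = 1`.
#' @export
genuine_vs_pseudo_test <- function(cohort, genuine = "strength",
                                   pseudo = "pseudo_mean") {
  g <- cohort[[genuine]]
  q <- cohort[[pseudo]]
  if (is.null(g) || is.null(q)) {
    stop_input("`cohort` must contain the genuine and pseudo strength columns.")
  }
  ok <- complete.cases(g, q)
  g <- g[ok]; q <- q[ok]
  n <- length(g)
  if (n < 3L) stop_input("Need at least 3 complete genuine/pseudo pairs.")
  d <- g - q
  if (sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.xmin)) {
    tt <- if (mean(d) == 0) {
      list(statistic = 0, parameter = n - 1, p.value = 1)
    } else {
      list(statistic = sign(mean(d)) * Inf, parameter = n - 1, p.value = 0)
    }
    degenerate <- TRUE
  } else {
    fit <- t.test(g, q, paired = TRUE)
    tt <- list(statistic = unname(fit$statistic),
               parameter = unname(fit$parameter), p.value = fit$p.value)
    degenerate <- FALSE
  }
  tibble(
    t = as.numeric(tt$statistic), df = as.numeric(tt$parameter),
    p = as.numeric(tt$p.value),
    mean_genuine = mean(g), sd_genuine = sd(g),
    mean_pseudo = mean(q), sd_pseudo = sd(q),
    mean_diff = mean(d), n = n, degenerate = degenerate
  )
}
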