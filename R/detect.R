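# Smoothing per-frame classifier scores into bouts.
#
# Frame-by-frame classification fragments short behaviors (lunges and
# headbutts last only a few frames) and the edges of longer ones. The
# smoothing applies, in order: (1) threshold -- a frame is "on" iff its
# score is strictly above the detection threshold; (2) maximum-gap filling
# -- every maximal run of "off" frames no longer than max_gap with "on"
# frames on both sides becomes "on" (scores kept intact; edge gaps are
# never filled, and gaps longer than max_gap are never filled even
# partially); (3) minimum bout length -- maximal "on" runs shorter than
# min_bout_len are discarded.

#' Smoothing parameters for bout detection
#'
#' @param threshold Score cutoff; a frame is on when `score > threshold`
#'   (strict, so exact-boundary scores are reproducible). Default 0.1, the
#'   detection threshold used for evaluation.
#' @param max_gap Maximum length (frames, >= 0) of an off-run to fill when
#'   flanked by on frames.
#' @param min_bout_len Minimum bout duration in frames (>= 1).
#' @return A list of class `"smoothing_params"`.
#' @export
smoothing_params <- function(threshold = 0.1, max_gap = 1L,
                             min_bout_len = 1L) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold))
    stop_value("threshold must be a single finite number")
  if (max_gap < 0 || max_gap != as.integer(max_gap))
    stop_value("max_gap must be an integer >= 0")
  if (min_bout_len < 1 || min_bout_len != as.integer(min_bout_len))
    stop_value("min_bout_len must be an integer >= 1")
  structure(list(threshold = threshold, max_gap = as.integer(max_gap),
                 min_bout_len = as.integer(min_bout_len)),
            class = "smoothing_params")
}

#' @export
print.smoothing_params <- function(x, ...) {
  cat(sprintf("smoothing: threshold > %g, fill gaps <= %d frames, ",
              x$threshold, x$max_gap),
      sprintf("keep bouts >= %d frames\n", x$min_bout_len), sep = "")
  invisible(x)
}

#' Detect classifier bouts in one score track
#'
#' Applies threshold, maximum-gap filling and minimum-bout-length filtering
#' to a per-frame score vector. The average score of a bout is the mean of
#' the raw frame scores over the bout extent, filled gap frames included
#' with their original (sub-threshold) scores.
#'
#' @param scores Numeric vector of per-frame classifier scores (finite).
#' @param params [smoothing_params()].
#' @return Data.frame with one row per bout: `start_frame`, `end_frame`,
#'   `avg_score`, `n_filled_gap_frames`. Zero rows when nothing passes.
#' @export
detect_bouts <- function(scores, params = smoothing_params()) {
  stopifnot(inherits(params, "smoothing_params"))
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      avg_score = numeric(0),
                      n_filled_gap_frames = integer(0))
  if (length(scores) == 0L) return(empty)
  if (any(!is.finite(scores)))
    stop_value("detect_bouts: non-finite score at frame ",
               which(!is.finite(scores))[1])
  on <- scores > params$threshold
  filled <- logical(length(on))
  if (params$max_gap > 0L && any(on)) {
    r <- rle(on)
    k <- length(r$lengths)
    if (k >= 3L) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      fill <- which(!r$values & r$lengths <= params$max_gap &
                      seq_len(k) > 1L & seq_len(k) < k)
      for (i in fill) {
        on[starts[i]:ends[i]] <- TRUE
        filled[starts[i]:ends[i]] <- TRUE
      }
    }
  }
  if (!any(on)) return(empty)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= params$min_bout_len)
  if (length(keep) == 0L) return(empty)
  data.frame(
    start_frame = starts[keep],
    end_frame = ends[keep],
    avg_score = vapply(keep, function(i)
      mean(scores[starts[i]:ends[i]]), 0),
    n_filled_gap_frames = vapply(keep, function(i)
      sum(filled[starts[i]:ends[i]]), 0L))
}

#' Detect bouts for every track in a dataset
#'
#' @param tracks Track table from [read_scores()] / [as_score_tracks()].
#' @inheritParams detect_bouts
#' @return Data.frame of classifier bouts with `movie_id`, `fly_id`,
#'   `behavior`, `start_frame`, `end_frame`, `avg_score`,
#'   `n_filled_gap_frames`.
#' @export
detect_all_bouts <- function(tracks, params = smoothing_params()) {
  pieces <- lapply(seq_len(nrow(tracks)), function(i) {
    b <- detect_bouts(tracks$scores[[i]], params)
    if (nrow(b) == 0L) return(NULL)
    cbind(data.frame(movie_id = tracks$movie_id[i],
                     fly_id = tracks$fly_id[i],
                     behavior = tracks$behavior[i],
                     stringsAsFactors = FALSE), b)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L)
    return(data.frame(movie_id = character(0), fly_id = character(0),
                      behavior = character(0), start_frame = integer(0),
                      end_frame = integer(0), avg_score = numeric(0),
                      n_filled_gap_frames = integer(0)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Minimum bout length retaining a fraction of human bouts
#'
#' Chooses the minimum-bout-length filter from the human bout-duration
#' distribution: the largest integer L such that at least `keep_fraction`
#' of human-annotated bouts have duration >= L frames (i.e. the filter
#' eliminates only bouts shorter than at least that fraction of the
#' manually annotated bouts; default 98%).
#'
#' @param combined Combined-bout data.frame, or a numeric vector of
#'   durations in frames.
#' @param keep_fraction Fraction in (0, 1] of human bouts to keep.
#' @return Integer L in frames.
#' @export
derive_min_bout_length <- function(combined, keep_fraction = 0.98) {
  d <- if (is.numeric(combined)) combined
       else combined$end_frame - combined$start_frame + 1L
  if (length(d) == 0L)
    stop_value("derive_min_bout_length: empty bout set")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_value("keep_fraction must be in (0, 1]")
  k <- ceiling(keep_fraction * length(d))
  as.integer(sort(d, decreasing = TRUE)[k])
}
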