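# Matching combined human bouts against smoothed classifier bouts.
#
# A human bout is "matched" (true positive) when any classifier bout
# overlaps it by >= 1 frame. Matching is referenced to human bouts:
# several classifier bouts overlapping one human bout collectively count
# as one match (the average classifier score is taken over the union of
# their frames); one classifier bout overlapping several human bouts
# yields one match per human bout, each assigned that bout's single
# average score. A human bout with no overlap is a false negative and
# receives a virtual classifier bout spanning its extent (average score =
# mean raw frame score there); a classifier bout with no overlap is a
# false positive and receives a virtual human bout with combined score 0.

#' Match human and classifier bouts for one track
#'
#' @param human Combined-bout data.frame for one (movie, fly, behavior)
#'   (needs `start_frame`, `end_frame`, `representative_score`).
#' @param classifier Classifier-bout data.frame for the same track (needs
#'   `start_frame`, `end_frame`, `avg_score`).
#' @param scores Numeric per-frame score vector for the track (used for
#'   union averages over multi-bout matches and for virtual bouts).
#' @return Match-record data.frame: `category` (TP/FN/FP), `human_score`
#'   (0 iff FP), `avg_classifier_score`, `human_start`, `human_end`
#'   (NA for FP), `classifier_start`, `classifier_end` (NA for FN), and a
#'   list-column `classifier_refs` of matched classifier-bout row indices.
#' @export
match_bouts <- function(human, classifier, scores) {
  if (nrow(classifier) > 0L && max(classifier$end_frame) > length(scores))
    stop_value("match_bouts: classifier bout ends at frame ",
               max(classifier$end_frame), " but track has only ",
               length(scores), " frames")
  if (nrow(human) > 0L && max(human$end_frame) > length(scores))
    stop_value("match_bouts: human bout ends beyond track length")
  nh <- nrow(human); nc <- nrow(classifier)
  overlaps <- function(hs, he) {
    if (nc == 0L) return(integer(0))
    which(classifier$start_frame <= he & classifier$end_frame >= hs)
  }
  rows <- list()
  matched_c <- logical(nc)
  for (i in seq_len(nh)) {
    hs <- human$start_frame[i]; he <- human$end_frame[i]
    ov <- overlaps(hs, he)
    if (length(ov) > 0L) {
      matched_c[ov] <- TRUE
      fr <- sort(unique(unlist(lapply(ov, function(j)
        classifier$start_frame[j]:classifier$end_frame[j]))))
      rows[[length(rows) + 1L]] <- list(
        category = "TP", human_score = human$representative_score[i],
        avg_classifier_score = mean(scores[fr]),
        human_start = hs, human_end = he,
        classifier_start = min(classifier$start_frame[ov]),
        classifier_end = max(classifier$end_frame[ov]),
        classifier_refs = ov)
    } else {
      # virtual classifier bout over the human extent
      rows[[length(rows) + 1L]] <- list(
        category = "FN", human_score = human$representative_score[i],
        avg_classifier_score = mean(scores[hs:he]),
        human_start = hs, human_end = he,
        classifier_start = NA_integer_, classifier_end = NA_integer_,
        classifier_refs = integer(0))
    }
  }
  for (j in which(!matched_c)) {
    rows[[length(rows) + 1L]] <- list(
      category = "FP", human_score = 0L,
      avg_classifier_score = classifier$avg_score[j],
      human_start = NA_integer_, human_end = NA_integer_,
      classifier_start = classifier$start_frame[j],
      classifier_end = classifier$end_frame[j],
      classifier_refs = j)
  }
  out <- data.frame(
    category = vapply(rows, `[[`, "", "category"),
    human_score = vapply(rows, function(r) as.integer(r$human_score), 0L),
    avg_classifier_score = vapply(rows, `[[`, 0, "avg_classifier_score"),
    human_start = vapply(rows, function(r) as.integer(r$human_start), 0L),
    human_end = vapply(rows, function(r) as.integer(r$human_end), 0L),
    classifier_start = vapply(rows, function(r)
      as.integer(r$classifier_start), 0L),
    classifier_end = vapply(rows, function(r)
      as.integer(r$classifier_end), 0L),
    stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    out <- out[0, , drop = FALSE]
  out$classifier_refs <- lapply(rows, `[[`, "classifier_refs")
  out
}

#' Match bouts across a whole dataset
#'
#' Runs [match_bouts()] per (movie, fly, behavior) track and binds the
#' records with their identifiers.
#'
#' @param combined Combined human bouts ([combine_annotations()]).
#' @param classifier_bouts Classifier bouts ([detect_all_bouts()]).
#' @param tracks Score-track table (the matching universe: every track in
#'   `tracks` is processed, so classifier bouts on tracks without human
#'   annotation become FPs).
#' @return Match-record data.frame with `movie_id`, `fly_id`, `behavior`
#'   prepended.
#' @export
match_all_bouts <- function(combined, classifier_bouts, tracks) {
  pieces <- lapply(seq_len(nrow(tracks)), function(i) {
    m <- tracks$movie_id[i]; f <- tracks$fly_id[i]; beh <- tracks$behavior[i]
    h <- combined[combined$movie_id == m & combined$fly_id == f &
                    combined$behavior == beh, , drop = FALSE]
    cb <- classifier_bouts[classifier_bouts$movie_id == m &
                             classifier_bouts$fly_id == f &
                             classifier_bouts$behavior == beh, , drop = FALSE]
    rec <- match_bouts(h, cb, tracks$scores[[i]])
    if (nrow(rec) == 0L) return(NULL)
    cbind(data.frame(movie_id = m, fly_id = f, behavior = beh,
                     stringsAsFactors = FALSE), rec)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L) {
    out <- data.frame(movie_id = character(0), fly_id = character(0),
                      behavior = character(0), category = character(0),
                      human_score = integer(0),
                      avg_classifier_score = numeric(0),
                      human_start = integer(0), human_end = integer(0),
                      classifier_start = integer(0),
                      classifier_end = integer(0))
    out$classifier_refs <- list()
    return(out)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Frame-based matching
#'
#' Classifies each frame against the raw thresholded score (smoothing is a
#' bout-level construct; set `use_bouts = TRUE` to instead declare a frame
#' "on" when it lies inside a smoothed classifier bout, for sensitivity
#' analysis): TP when the score is strictly above threshold and the
#' combined human score is >= 1; FN when annotated but below threshold;
#' FP when above threshold with no annotation; TN otherwise.
#'
#' @param frame_scores Integer vector of combined human frame scores (0-6).
#' @param scores Numeric per-frame classifier scores, same length.
#' @param threshold Detection threshold (strict `>`).
#' @param use_bouts Optional classifier-bout data.frame; when supplied,
#'   "above threshold" is replaced by bout membership.
#' @return Data.frame: `frame`, `human_score`, `score`, `category`.
#' @export
match_frames <- function(frame_scores, scores, threshold = 0.1,
                         use_bouts = NULL) {
  if (length(frame_scores) != length(scores))
    stop_value("match_frames: human series (", length(frame_scores),
               ") and score track (", length(scores),
               ") differ in length")
  on <- if (is.null(use_bouts)) {
    scores > threshold
  } else {
    v <- logical(length(scores))
    for (i in seq_len(nrow(use_bouts)))
      v[use_bouts$start_frame[i]:use_bouts$end_frame[i]] <- TRUE
    v
  }
  human <- frame_scores >= 1L
  category <- ifelse(on & human, "TP",
                     ifelse(human, "FN", ifelse(on, "FP", "TN")))
  data.frame(frame = seq_along(scores),
             human_score = as.integer(frame_scores),
             score = scores, category = category,
             stringsAsFactors = FALSE)
}
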