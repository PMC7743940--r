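# Combined human annotation: union-merge of two observers' graded bouts.
#
# Two bouts are declared overlapping when they share >= 1 frame (17 ms at
# 60 fps). Connected components of the bipartite overlap graph between the
# two observers become one combined bout whose extent is the union. Each
# overlapping (A-bout, B-bout) pair contributes one score record equal to
# the sum of the two confidences (1-6 scale); a bout seen by one observer
# only carries a single record equal to that observer's confidence. When
# one observer split a region that the other annotated as a single bout,
# the split pieces are counted as separate bout records, and the maximum
# record is the region's representative score.

#' Merge two observers' bouts for one (movie, fly, behavior)
#'
#' Low-level merge of two internally non-overlapping bout sets for the same
#' movie, fly and behavior. Most callers want [combine_annotations()], which
#' applies this per group across a full annotation table.
#'
#' @param bouts_a,bouts_b Data.frames with columns `start_frame`,
#'   `end_frame`, `confidence` (either may have zero rows). All rows must
#'   refer to the same (movie, fly, behavior); supply those identifiers via
#'   the usual columns or through `ids`.
#' @param ids Optional named list/character giving `movie_id`, `fly_id`,
#'   `behavior` for the output when the inputs carry no id columns.
#' @return A combined-bout data.frame: `movie_id`, `fly_id`, `behavior`,
#'   `start_frame`, `end_frame`, `observer_count`, `n_records`,
#'   `representative_score`, plus list-columns `score_records`, `conf_a`,
#'   `conf_b` (per-record observer confidences; 0 for the absent observer).
#' @export
merge_observer_bouts <- function(bouts_a, bouts_b, ids = NULL) {
  take_ids <- function(df) {
    if (!is.null(ids)) return(as.list(ids)[c("movie_id", "fly_id", "behavior")])
    if (all(c("movie_id", "fly_id", "behavior") %in% names(df)) &&
        nrow(df) > 0L)
      return(list(movie_id = df$movie_id[1], fly_id = df$fly_id[1],
                  behavior = df$behavior[1]))
    NULL
  }
  id <- take_ids(bouts_a) %||% take_ids(bouts_b) %||%
    list(movie_id = NA_character_, fly_id = NA_character_,
         behavior = NA_character_)
  for (df in list(bouts_a, bouts_b)) {
    if (nrow(df) == 0L) next
    if (length(unique(df$movie_id %||% id$movie_id)) > 1L ||
        length(unique(df$behavior %||% id$behavior)) > 1L ||
        length(unique(df$fly_id %||% id$fly_id)) > 1L)
      stop_value("merge_observer_bouts: mixed movies/flies/behaviors in one ",
                 "call; merge one (movie, fly, behavior) group at a time")
  }
  check_nonoverlap <- function(df, who) {
    if (nrow(df) < 2L) return()
    o <- order(df$start_frame)
    if (any(df$start_frame[o][-1] <= df$end_frame[o][-nrow(df)]))
      stop_value("merge_observer_bouts: observer ", who,
                 " bouts overlap each other; resolve on ingest")
  }
  check_nonoverlap(bouts_a, "A"); check_nonoverlap(bouts_b, "B")

  na <- nrow(bouts_a); nb <- nrow(bouts_b)
  sa <- bouts_a$start_frame; ea <- bouts_a$end_frame
  sb <- bouts_b$start_frame; eb <- bouts_b$end_frame
  # overlap pairs (>= 1 shared frame)
  pairs <- NULL
  if (na > 0L && nb > 0L) {
    grid <- expand.grid(i = seq_len(na), j = seq_len(nb))
    keep <- sa[grid$i] <= eb[grid$j] & sb[grid$j] <= ea[grid$i]
    pairs <- grid[keep, , drop = FALSE]
  }
  # connected components over nodes A1..Ana, B1..Bnb
  parent <- seq_len(na + nb)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (!is.null(pairs) && nrow(pairs) > 0L)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs$i[k]); rb <- find(na + pairs$j[k])
      if (ra != rb) parent[rb] <- ra
    }
  comp <- vapply(seq_len(na + nb), find, 0L)
  comps <- unname(split(seq_len(na + nb), comp))

  rows <- lapply(comps, function(nodes) {
    ai <- nodes[nodes <= na]
    bi <- nodes[nodes > na] - na
    ext_s <- min(c(sa[ai], sb[bi]))
    ext_e <- max(c(ea[ai], eb[bi]))
    if (length(ai) > 0L && length(bi) > 0L) {
      sub <- pairs[pairs$i %in% ai & pairs$j %in% bi, , drop = FALSE]
      sub <- sub[order(sa[sub$i], sb[sub$j]), , drop = FALSE]
      ca <- bouts_a$confidence[sub$i]
      cb <- bouts_b$confidence[sub$j]
      recs <- as.integer(ca + cb)
      obs <- 2L
    } else if (length(ai) > 0L) {
      ca <- bouts_a$confidence[ai]; cb <- 0L
      recs <- as.integer(ca)
      obs <- 1L
    } else {
      ca <- 0L; cb <- bouts_b$confidence[bi]
      recs <- as.integer(cb)
      obs <- 1L
    }
    list(start_frame = ext_s, end_frame = ext_e, observer_count = obs,
         score_records = recs,
         conf_a = as.integer(rep_len(ca, length(recs))),
         conf_b = as.integer(rep_len(cb, length(recs))))
  })
  out <- data.frame(
    movie_id = rep(id$movie_id, length(rows)),
    fly_id = rep(id$fly_id, length(rows)),
    behavior = rep(id$behavior, length(rows)),
    start_frame = vapply(rows, `[[`, 0, "start_frame"),
    end_frame = vapply(rows, `[[`, 0, "end_frame"),
    observer_count = vapply(rows, `[[`, 0L, "observer_count"),
    stringsAsFactors = FALSE)
  out$score_records <- lapply(rows, `[[`, "score_records")
  out$conf_a <- lapply(rows, `[[`, "conf_a")
  out$conf_b <- lapply(rows, `[[`, "conf_b")
  out$n_records <- vapply(out$score_records, length, 0L)
  out$representative_score <- vapply(out$score_records,
                                     function(r) max(as.integer(r)), 0L)
  out <- out[order(out$start_frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build combined human annotations from a two-observer table
#'
#' Applies the union-merge to every (movie, fly, behavior) group of a
#' validated annotation table. Exactly one or two observers per movie are
#' supported (as in a two-annotator study design); more raise an error.
#' Within a movie, observers are ordered by sorted `observer_id`, so the
#' per-record `conf_a`/`conf_b` columns refer to the alphabetically first
#' and second observer.
#'
#' @param annotations Data.frame from [read_annotations()]/[as_annotations()].
#' @return Combined-bout data.frame as in [merge_observer_bouts()], ordered
#'   by movie, fly, behavior, start frame.
#' @export
combine_annotations <- function(annotations) {
  if (nrow(annotations) == 0L)
    return(merge_observer_bouts(annotations, annotations,
                                ids = list(movie_id = character(0)))[0, ])
  out <- list()
  for (m in unique(annotations$movie_id)) {
    sub_m <- annotations[annotations$movie_id == m, , drop = FALSE]
    obs <- sort(unique(sub_m$observer_id))
    if (length(obs) > 2L)
      stop_value("combine_annotations: movie '", m, "' has ", length(obs),
                 " observers; exactly two (or one) are supported")
    key <- interaction(sub_m$fly_id, sub_m$behavior, drop = TRUE)
    for (rows in split(seq_len(nrow(sub_m)), key)) {
      g <- sub_m[rows, , drop = FALSE]
      a <- g[g$observer_id == obs[1], , drop = FALSE]
      b <- if (length(obs) == 2L) g[g$observer_id == obs[2], , drop = FALSE]
           else g[0, , drop = FALSE]
      out[[length(out) + 1L]] <- merge_observer_bouts(
        a, b, ids = list(movie_id = m, fly_id = g$fly_id[1],
                         behavior = g$behavior[1]))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$movie_id, res$fly_id, res$behavior, res$start_frame), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flatten combined bouts to one row per score record
#'
#' Split annotation regions contribute one row per score record (the
#' bout-counting unit for score-distribution summaries), each carrying the
#' two observers' per-record confidences.
#'
#' @param combined Output of [combine_annotations()].
#' @return Data.frame with columns `movie_id`, `fly_id`, `behavior`,
#'   `start_frame`, `end_frame`, `conf_a`, `conf_b`, `score`,
#'   `observer_count`, `bout_index`.
#' @export
score_record_table <- function(combined) {
  n <- combined$n_records
  data.frame(
    movie_id = rep(combined$movie_id, n),
    fly_id = rep(combined$fly_id, n),
    behavior = rep(combined$behavior, n),
    start_frame = rep(combined$start_frame, n),
    end_frame = rep(combined$end_frame, n),
    conf_a = unlist(combined$conf_a, use.names = FALSE),
    conf_b = unlist(combined$conf_b, use.names = FALSE),
    score = unlist(combined$score_records, use.names = FALSE),
    observer_count = rep(combined$observer_count, n),
    bout_index = rep(seq_len(nrow(combined)), n),
    stringsAsFactors = FALSE)
}

#' Frame-wise combined human score for one track
#'
#' Sums the two observers' per-frame confidences: a frame inside an
#' observer's bout carries that bout's confidence, 0 otherwise, and the
#' combined frame score is the sum (0-6).
#'
#' @inheritParams merge_observer_bouts
#' @param n_frames Track length in frames.
#' @return Integer vector of length `n_frames` with values 0-6.
#' @export
frame_combined_scores <- function(bouts_a, bouts_b, n_frames) {
  if (n_frames < 1) stop_value("n_frames must be >= 1")
  paint <- function(df) {
    v <- integer(n_frames)
    if (nrow(df) > 0L) {
      if (any(df$end_frame > n_frames))
        stop_value("frame_combined_scores: bout end ", max(df$end_frame),
                   " exceeds n_frames ", n_frames)
      for (i in seq_len(nrow(df)))
        v[df$start_frame[i]:df$end_frame[i]] <- df$confidence[i]
    }
    v
  }
  paint(bouts_a) + paint(bouts_b)
}

#' Frame-wise combined scores for every track in a dataset
#'
#' @param annotations Validated annotation table (<= 2 observers per movie).
#' @param movies Movie metadata supplying `n_frames` per movie.
#' @param behaviors Behaviors to include (default: all present).
#' @param flies Optional data.frame (`movie_id`, `fly_id`) enumerating the
#'   fly tracks to emit; defaults to the flies present in `annotations`.
#' @return Data.frame with one row per (movie, fly, behavior) and a
#'   list-column `frame_scores` (integer 0-6 per frame).
#' @export
frame_score_series <- function(annotations, movies, behaviors = NULL,
                               flies = NULL) {
  behaviors <- behaviors %||% sort(unique(annotations$behavior))
  if (is.null(flies)) {
    flies <- unique(annotations[, c("movie_id", "fly_id")])
  }
  flies <- flies[order(flies$movie_id, flies$fly_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(flies))) {
    m <- flies$movie_id[i]; f <- flies$fly_id[i]
    nf <- movies$n_frames[match(m, movies$movie_id)]
    if (is.na(nf)) stop_value("frame_score_series: movie '", m,
                              "' missing from metadata")
    sub <- annotations[annotations$movie_id == m & annotations$fly_id == f, ,
                       drop = FALSE]
    obs <- sort(unique(annotations$observer_id[annotations$movie_id == m]))
    for (beh in behaviors) {
      g <- sub[sub$behavior == beh, , drop = FALSE]
      a <- g[g$observer_id == obs[1], , drop = FALSE]
      b <- if (length(obs) >= 2L) g[g$observer_id == obs[2], , drop = FALSE]
           else g[0, , drop = FALSE]
      rows[[length(rows) + 1L]] <- list(
        movie_id = m, fly_id = f, behavior = beh,
        frame_scores = frame_combined_scores(a, b, nf))
    }
  }
  out <- data.frame(
    movie_id = vapply(rows, `[[`, "", "movie_id"),
    fly_id = vapply(rows, `[[`, "", "fly_id"),
    behavior = vapply(rows, `[[`, "", "behavior"),
    stringsAsFactors = FALSE)
  out$frame_scores <- lapply(rows, `[[`, "frame_scores")
  out
}

#' Summary statistics of combined annotations
#'
#' Per behavior: total score records (the bout-counting unit), counts by
#' pair type, the 4x4 grid of observer-A x observer-B per-record
#' confidences (0 = not annotated by that observer; cell (0,0) is
#' structurally empty), the fraction of records with combined score 4-6,
#' the fraction annotated by a single observer, and bout-duration medians.
#' When frame-score series are supplied, the analogous frame-based
#' fractions are included.
#'
#' @param combined Output of [combine_annotations()].
#' @param movies Movie metadata (for pair types and fps).
#' @param frames Optional [frame_score_series()] output for frame-based
#'   fractions.
#' @return A list of class `"annotation_summary"`, one element per behavior.
#' @export
summarize_annotations <- function(combined, movies, frames = NULL) {
  recs <- score_record_table(combined)
  idx <- match(recs$movie_id, movies$movie_id)
  if (anyNA(idx))
    stop_value("summarize_annotations: movie '",
               recs$movie_id[which(is.na(idx))[1]], "' missing from metadata")
  recs$pair_type <- movies$pair_type[idx]
  behaviors <- sort(unique(c(combined$behavior,
                             if (!is.null(frames)) frames$behavior)))
  out <- lapply(behaviors, function(beh) {
    r <- recs[recs$behavior == beh, , drop = FALSE]
    cb <- combined[combined$behavior == beh, , drop = FALSE]
    grid <- matrix(0L, 4, 4, dimnames = list(A = 0:3, B = 0:3))
    if (nrow(r) > 0L)
      for (k in seq_len(nrow(r)))
        grid[r$conf_a[k] + 1L, r$conf_b[k] + 1L] <-
          grid[r$conf_a[k] + 1L, r$conf_b[k] + 1L] + 1L
    n <- nrow(r)
    res <- list(
      behavior = beh,
      n_records = n,
      n_combined_bouts = nrow(cb),
      by_pair_type = if (n > 0L) table(factor(r$pair_type, PAIR_TYPES))
                     else table(factor(character(0), PAIR_TYPES)),
      grid = grid,
      frac_score_4_6 = if (n > 0L) mean(r$score >= 4L) else 0,
      frac_one_observer = if (n > 0L) mean(r$observer_count == 1L) else 0,
      duration = if (nrow(cb) > 0L)
        bout_duration_stats(cb, fps = movies$fps[match(cb$movie_id,
                                                       movies$movie_id)])
        else NULL)
    if (!is.null(frames)) {
      fs <- unlist(frames$frame_scores[frames$behavior == beh],
                   use.names = FALSE)
      nz <- fs[fs > 0L]
      res$frame_frac_score_4_6 <- if (length(nz)) mean(nz >= 4L) else 0
      # one-observer frames: nonzero frames covered by a single observer.
      # A frame sum of 1-3 can only arise from one observer except sum 2 or
      # 3 from 1+1/1+2; those need per-observer cover, supplied separately.
      res$frame_frac_nonzero <- if (length(fs)) mean(fs > 0L) else 0
    }
    res
  })
  names(out) <- behaviors
  structure(out, class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  for (s in x) {
    cat(sprintf("%s: %d bout records (%d merged regions)\n", s$behavior,
                s$n_records, s$n_combined_bouts))
    cat(sprintf("  combined score 4-6: %.1f%%   single-observer: %.1f%%\n",
                100 * s$frac_score_4_6, 100 * s$frac_one_observer))
    if (!is.null(s$duration))
      cat(sprintf("  median bout duration: %g frames (%d ms)\n",
                  s$duration$median_frames, s$duration$median_ms))
  }
  invisible(x)
}

#' Bout-duration statistics
#'
#' Durations of combined annotation regions in frames
#' (`end - start + 1`) and milliseconds (1 frame = 1000/fps ms; 16.67 ms at
#' 60 fps, reported rounded to the nearest ms).
#'
#' @param combined Combined-bout data.frame (or any data.frame with
#'   `start_frame`/`end_frame`).
#' @param fps Frames per second (> 0); a scalar, or one value per bout when
#'   movies differ in frame rate.
#' @return List: `durations_frames`, `median_frames`, `median_ms`,
#'   `histogram` (table of frame durations).
#' @export
bout_duration_stats <- function(combined, fps = 60) {
  if (nrow(combined) == 0L)
    stop_value("bout_duration_stats: empty bout set")
  if (any(fps <= 0)) stop_value("fps must be > 0")
  d <- combined$end_frame - combined$start_frame + 1L
  ms <- d * 1000 / fps
  list(durations_frames = d,
       median_frames = stats::median(d),
       median_ms = as.integer(round(stats::median(ms))),
       histogram = table(d))
}
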