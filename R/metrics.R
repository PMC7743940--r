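# Precision/recall and related agreement metrics.
#
# Precision = TP / (TP + FP): the fraction of classifier detections that a
# human also annotated. Recall = TP / (TP + FN): the fraction of human
# annotations the classifier detected. Both are bout-referenced here; the
# frame-based analogues use match_frames() categories.

#' Precision and recall from match records
#'
#' @param records Match-record data.frame (bout-based from
#'   [match_all_bouts()] or frame-based from [match_frames()]; any
#'   data.frame with a `category` column).
#' @return List of class `"metrics_report"`: `tp`, `fn`, `fp`, `precision`
#'   (NA when TP + FP = 0 -- undefined, never silently 0 or 1), `recall`
#'   (NA when TP + FN = 0), `recall_x_precision`.
#' @export
precision_recall <- function(records) {
  tp <- sum(records$category == "TP")
  fn <- sum(records$category == "FN")
  fp <- sum(records$category == "FP")
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  structure(list(tp = tp, fn = fn, fp = fp,
                 precision = precision, recall = recall,
                 recall_x_precision = if (is.na(precision) || is.na(recall))
                   NA_real_ else recall * precision),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("TP %d  FN %d  FP %d | precision %s  recall %s\n",
              x$tp, x$fn, x$fp, fmt(x$precision), fmt(x$recall)))
  invisible(x)
}

#' Recall stratified by combined human score
#'
#' Bins TP and FN bouts by their combined human score (1-6, the
#' representative score for split regions) and computes recall within each
#' bin. Scores absent from the data are omitted, not zero-filled.
#'
#' @param records Match-record data.frame.
#' @return Named numeric vector, names = scores present, values = recall.
#' @export
recall_by_score <- function(records) {
  r <- records[records$category %in% c("TP", "FN"), , drop = FALSE]
  if (nrow(r) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- tapply(r$category == "TP", factor(r$human_score), mean)
  stats::setNames(as.numeric(tab), names(tab))
}

#' False-positive rate per pair type
#'
#' False-positive bouts per minute of evaluated video, split by the movie
#' sex combination. The denominator is the total duration of the supplied
#' movies of that type with role `"evaluation"` (all movies of the type
#' when no movie carries a training role); raw FP counts and minutes are
#' returned alongside the rates.
#'
#' @param records Match-record data.frame (with `movie_id`).
#' @param movies Movie metadata.
#' @return Data.frame: `pair_type`, `n_fp`, `minutes`, `fp_per_min`.
#' @export
fp_rate_by_pair_type <- function(records, movies) {
  idx <- match(records$movie_id, movies$movie_id)
  if (anyNA(idx))
    stop_value("fp_rate_by_pair_type: movie '",
               records$movie_id[which(is.na(idx))[1]],
               "' missing from metadata")
  eval_movies <- if (any(movies$role == "training"))
    movies[movies$role == "evaluation", , drop = FALSE] else movies
  minutes <- tapply(eval_movies$n_frames / eval_movies$fps / 60,
                    factor(eval_movies$pair_type, PAIR_TYPES), sum,
                    default = 0)
  fp <- records[records$category == "FP", , drop = FALSE]
  fp_type <- movies$pair_type[match(fp$movie_id, movies$movie_id)]
  n_fp <- table(factor(fp_type, PAIR_TYPES))
  present <- names(minutes)[minutes > 0 | n_fp > 0]
  zero_time <- present[minutes[present] == 0]
  if (length(zero_time) > 0L)
    stop_value("fp_rate_by_pair_type: pair type '", zero_time[1],
               "' has false positives but zero evaluated minutes")
  data.frame(pair_type = present,
             n_fp = as.integer(n_fp[present]),
             minutes = as.numeric(minutes[present]),
             fp_per_min = as.numeric(n_fp[present] / minutes[present]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Grid search over smoothing parameters
#'
#' Runs the full detect-match-metrics pipeline for every combination of
#' threshold, maximum gap and minimum bout length, and ranks the
#' combinations by recall x precision (descending; the near-maximum region
#' of this product is where the recall/precision trade-off flattens).
#' Ties break deterministically by ascending (threshold, min_bout_len,
#' max_gap).
#'
#' @param combined Combined human bouts.
#' @param tracks Score-track table.
#' @param thresholds,max_gaps,min_bout_lens Numeric vectors spanned by the
#'   grid.
#' @return Data.frame sorted by the objective, one row per grid point:
#'   parameters, TP/FN/FP counts, `precision`, `recall`,
#'   `recall_x_precision`, `rank`.
#' @export
parameter_grid_search <- function(combined, tracks,
                                  thresholds = c(0, 0.1, 0.2, 0.3),
                                  max_gaps = c(0L, 1L, 2L, 4L),
                                  min_bout_lens = c(1L, 2L, 3L, 5L)) {
  grid <- expand.grid(threshold = thresholds, max_gap = max_gaps,
                      min_bout_len = min_bout_lens,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop_value("parameter_grid_search: empty grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- smoothing_params(grid$threshold[i], grid$max_gap[i],
                          grid$min_bout_len[i])
    m <- tryCatch({
      cb <- detect_all_bouts(tracks, p)
      precision_recall(match_all_bouts(combined, cb, tracks))
    }, error = function(e)
      stop_value("grid point (threshold=", grid$threshold[i], ", max_gap=",
                 grid$max_gap[i], ", min_bout_len=", grid$min_bout_len[i],
                 "): ", conditionMessage(e)))
    data.frame(threshold = grid$threshold[i], max_gap = grid$max_gap[i],
               min_bout_len = grid$min_bout_len[i], tp = m$tp, fn = m$fn,
               fp = m$fp, precision = m$precision, recall = m$recall,
               recall_x_precision = m$recall_x_precision)
  })
  out <- do.call(rbind, res)
  obj <- ifelse(is.na(out$recall_x_precision), -Inf, out$recall_x_precision)
  ord <- order(-obj, out$threshold, out$min_bout_len, out$max_gap)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-feature z-score profiles by annotation label
#'
#' Standardizes each tracker feature over all frames (global mean 0,
#' sd 1), splits frames into annotated (combined human score >= 1) and
#' unannotated, and summarizes each group's z-score distribution (median,
#' quartiles, 0.5 and 99.5 percentiles) and variance. Features with zero
#' global variance are flagged rather than propagated as NaN.
#'
#' @param features Data.frame of per-frame feature values; columns other
#'   than `movie_id`, `fly_id`, `frame` are treated as features unless
#'   `feature_cols` is given.
#' @param annotated Logical vector (one per feature row) marking frames
#'   with combined human score >= 1, or an integer frame-score vector.
#' @param feature_cols Optional explicit feature column names.
#' @return Data.frame: one row per feature x group with `median`, `q25`,
#'   `q75`, `p005`, `p995`, `variance`, `n`, `zero_variance`.
#' @export
feature_zscore_profiles <- function(features, annotated,
                                    feature_cols = NULL) {
  feature_cols <- feature_cols %||%
    setdiff(names(features), c("movie_id", "fly_id", "frame"))
  if (length(annotated) != nrow(features))
    stop_value("feature_zscore_profiles: 'annotated' must have one entry ",
               "per feature row")
  lab <- if (is.logical(annotated)) annotated else annotated >= 1
  groups <- if (any(lab)) list(annotated = lab, unannotated = !lab)
            else list(unannotated = !lab)
  rows <- list()
  for (fc in feature_cols) {
    v <- features[[fc]]
    s <- stats::sd(v)
    zero_var <- !is.finite(s) || s == 0
    z <- if (zero_var) rep(0, length(v)) else (v - mean(v)) / s
    for (g in names(groups)) {
      zz <- z[groups[[g]]]
      q <- if (length(zz) > 0L)
        stats::quantile(zz, c(0.005, 0.25, 0.5, 0.75, 0.995), names = FALSE)
        else rep(NA_real_, 5)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = fc, group = g, n = length(zz),
        median = q[3], q25 = q[2], q75 = q[4], p005 = q[1], p995 = q[5],
        variance = if (length(zz) > 1L) stats::var(zz) else 0,
        zero_variance = zero_var, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
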