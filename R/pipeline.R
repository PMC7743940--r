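# End-to-end pipeline: combine -> detect -> match -> metrics -> null.

#' Run the full benchmarking pipeline
#'
#' Builds combined human annotations, smooths classifier score tracks into
#' bouts, matches them, and computes the agreement metrics and (optionally)
#' the shuffled-score null comparison, per behavior.
#'
#' @param annotations Validated observer-bout table
#'   ([read_annotations()] / [as_annotations()]).
#' @param tracks Score-track table ([read_scores()] / [as_score_tracks()]).
#' @param movies Movie metadata ([read_movies()] / [as_movies()]).
#' @param params [smoothing_params()] used for bout detection.
#' @param behaviors Behaviors to evaluate (default: those present in the
#'   tracks).
#' @param n_shuffles Shuffled replicates for the null comparison; 0 skips
#'   it.
#' @param seed Base seed for shuffling (required when `n_shuffles > 0`).
#' @param outdir Optional directory; when given, every stage output is
#'   written as CSV/JSON together with a manifest recording parameters,
#'   seed and content hashes.
#' @return Object of class `"ethobench"`: list with `combined`,
#'   `classifier_bouts`, `match_records`, `frame_series`, `metrics` (per
#'   behavior), `recall_by_score`, `fp_rates`, `null` (per behavior, when
#'   requested), `params`, `seed`.
#' @examples
#' sim <- generate_dataset(synthetic_config(seed = 1,
#'   movies = default_sim_movies(n_frames = 3000L)))
#' fit <- run_pipeline(sim$annotations, sim$tracks, sim$movies,
#'                     params = smoothing_params(0.1, 1, 2),
#'                     n_shuffles = 10, seed = 1)
#' summary(fit)
#' @export
run_pipeline <- function(annotations, tracks, movies,
                         params = smoothing_params(),
                         behaviors = NULL, n_shuffles = 50L, seed = NULL,
                         outdir = NULL) {
  behaviors <- behaviors %||% sort(unique(tracks$behavior))
  annotations <- annotations[annotations$behavior %in% behaviors, ,
                             drop = FALSE]
  tracks <- tracks[tracks$behavior %in% behaviors, , drop = FALSE]
  if (n_shuffles > 0L && is.null(seed))
    stop_value("run_pipeline: seed is required when n_shuffles > 0")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_value("stage '", name, "': ", conditionMessage(e)))
  }
  combined <- stage("combine", combine_annotations(annotations))
  frame_series <- stage("combine", frame_score_series(
    annotations, movies,
    flies = unique(tracks[, c("movie_id", "fly_id")])))
  classifier_bouts <- stage("detect", detect_all_bouts(tracks, params))
  match_records <- stage("match", match_all_bouts(combined, classifier_bouts,
                                                  tracks))
  metrics <- list(); rbs <- list(); fp_rates <- list(); null <- list()
  for (beh in behaviors) {
    rec <- match_records[match_records$behavior == beh, , drop = FALSE]
    metrics[[beh]] <- stage("metrics", precision_recall(rec))
    rbs[[beh]] <- stage("metrics", recall_by_score(rec))
    fp_rates[[beh]] <- stage("metrics", fp_rate_by_pair_type(rec, movies))
    if (n_shuffles > 0L && any(rec$category %in% c("TP", "FN")) &&
        length(unique(rec$human_score[rec$category %in% c("TP", "FN")])) >= 2L)
      null[[beh]] <- stage("null", null_comparison(
        rec, shuffle_scores(rec, n_shuffles, base_seed = seed)))
  }
  fit <- structure(list(combined = combined, frame_series = frame_series,
                        classifier_bouts = classifier_bouts,
                        match_records = match_records, metrics = metrics,
                        recall_by_score = rbs, fp_rates = fp_rates,
                        null = null, params = params, seed = seed,
                        behaviors = behaviors, movies = movies),
                   class = "ethobench")
  if (!is.null(outdir)) write_report(fit, outdir)
  fit
}

#' Write pipeline outputs with a manifest
#'
#' @param fit An `"ethobench"` object.
#' @param outdir Output directory.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
write_report <- function(fit, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_table(df, path)
    files <<- c(files, path)
  }
  emit(fit$combined[, c("movie_id", "fly_id", "behavior", "start_frame",
                        "end_frame", "score_records", "representative_score",
                        "observer_count")], "combined_bouts.csv")
  emit(fit$classifier_bouts, "classifier_bouts.csv")
  emit(fit$match_records[, setdiff(names(fit$match_records), "density")],
       "match_records.csv")
  metrics_rows <- do.call(rbind, lapply(names(fit$metrics), function(beh) {
    m <- fit$metrics[[beh]]
    data.frame(behavior = beh, tp = m$tp, fn = m$fn, fp = m$fp,
               precision = m$precision, recall = m$recall)
  }))
  emit(metrics_rows, "metrics.csv")
  null_json <- lapply(fit$null, function(nr)
    list(observed_p = nr$observed_p, shuffled_p = nr$shuffled_p,
         recall_table = nr$recall_table))
  path <- file.path(outdir, "null_report.json")
  jsonlite::write_json(null_json, path, auto_unbox = TRUE, digits = NA)
  files <- c(files, path)
  manifest <- list(
    params = unclass(fit$params), seed = fit$seed,
    behaviors = fit$behaviors,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.ethobench <- function(x, ...) {
  cat("Behavior-classifier benchmark against combined human annotation\n")
  print(x$params)
  for (beh in names(x$metrics)) {
    cat(sprintf("%-15s ", beh)); print(x$metrics[[beh]])
  }
  invisible(x)
}

#' @export
summary.ethobench <- function(object, ...) {
  print(object)
  for (beh in names(object$recall_by_score)) {
    r <- object$recall_by_score[[beh]]
    if (length(r) == 0L) next
    cat(sprintf("%s recall by combined human score:\n", beh))
    cat(sprintf("  score %s: %5.1f%%\n", names(r), 100 * r), sep = "")
    if (!is.null(object$null[[beh]])) {
      nr <- object$null[[beh]]
      cat(sprintf("  observed KW p = %.3g vs %d shuffles (min %.3g)%s\n",
                  nr$observed_p, length(nr$shuffled_p), min(nr$shuffled_p),
                  if (nr$observed_below_all) " -- below all shuffles" else ""))
    }
  }
  invisible(object)
}

#' Plot recall by combined human score
#'
#' Base-graphics plot of confidence-stratified recall per behavior, with
#' the shuffled-null mean and 95% band overlaid when the null comparison
#' was run.
#'
#' @param x An `"ethobench"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ethobench <- function(x, ...) {
  behs <- names(x$recall_by_score)
  behs <- behs[vapply(x$recall_by_score, length, 0L) > 0L]
  if (length(behs) == 0L) stop_value("plot.ethobench: nothing to plot")
  old <- graphics::par(mfrow = c(1, length(behs)))
  on.exit(graphics::par(old))
  for (beh in behs) {
    r <- x$recall_by_score[[beh]]
    sc <- as.integer(names(r))
    graphics::plot(sc, 100 * r, type = "b", pch = 19, ylim = c(0, 100),
                   xlab = "combined human score", ylab = "recall (%)",
                   main = beh, ...)
    nr <- x$null[[beh]]
    if (!is.null(nr)) {
      tab <- nr$recall_table
      graphics::polygon(c(tab$score, rev(tab$score)),
                        100 * c(tab$lo, rev(tab$hi)),
                        col = grDevices::adjustcolor("grey", 0.4),
                        border = NA)
      graphics::lines(tab$score, 100 * tab$shuffled_mean, lty = 2)
    }
  }
  invisible(x)
}
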