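# Permutation null for the human-score / classifier-score correlation,
# plus the accompanying rank tests and t-based confidence intervals.
#
# The null model asks whether average classifier scores merely happen to
# line up with human combined scores: each shuffled replicate permutes the
# observed combined scores uniformly across the human-annotated (TP and
# FN) bouts -- so every replicate preserves the exact count of each score
# category -- while false positives stay false positives with score 0 and
# all classifier scores and TP/FN flags stay put.

#' Generate shuffled-score replicates
#'
#' @param records Match-record data.frame with at least one TP or FN bout.
#' @param n_reps Number of replicates (the evaluation used 50).
#' @param base_seed Integer seed; replicate r uses a deterministic stride
#'   from it (`base_seed + 7919 * r`), so a fixed base seed reproduces the
#'   full set bit-for-bit while the replicate streams stay disjoint from
#'   the small seed offsets the synthetic generator derives from the same
#'   master seed.
#' @return List of `n_reps` match-record data.frames.
#' @export
shuffle_scores <- function(records, n_reps = 50L, base_seed) {
  if (missing(base_seed) || is.null(base_seed))
    stop_value("shuffle_scores: base_seed is required (no silent ",
               "nondeterminism)")
  if (n_reps < 1L) stop_value("n_reps must be >= 1")
  idx <- which(records$category %in% c("TP", "FN"))
  if (length(idx) == 0L)
    stop_value("shuffle_scores: no human-annotated (TP/FN) bouts to shuffle")
  lapply(seq_len(n_reps), function(r) {
    set.seed((as.integer(base_seed) + 7919L * r) %% 2147483647L)
    shuffled <- records
    shuffled$human_score[idx] <- records$human_score[sample(idx)]
    shuffled
  })
}

#' Kruskal-Wallis test of score-group differences
#'
#' Rank-based one-way test (with tie correction) of whether average
#' classifier scores differ across combined human score groups. Thin
#' wrapper over [stats::kruskal.test()] returning the H statistic and the
#' chi-square p-value.
#'
#' @param values Numeric values (e.g. average classifier scores).
#' @param groups Grouping vector (e.g. combined human scores), same length.
#' @return List: `H`, `df`, `p`.
#' @export
kw_test <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L)
    stop_value("kw_test: need >= 2 non-empty groups, got ", nlevels(g))
  k <- stats::kruskal.test(values, g)
  list(H = unname(k$statistic), df = unname(k$parameter),
       p = unname(k$p.value))
}

#' Pairwise Mann-Whitney tests between neighboring score groups
#'
#' Two-sided Mann-Whitney U tests between each pair of neighboring
#' combined human scores present in the data (e.g. scores {2,3,5} give the
#' pairs 2-3 and 3-5), pooling TP and FN bouts of each score. P-values are
#' exact for small untied samples and use the normal approximation with
#' continuity and tie correction otherwise ([stats::wilcox.test()]); the
#' Bonferroni divisor is the number of pairs tested.
#'
#' @inheritParams kw_test
#' @param alpha Critical value before correction (default 0.01, the
#'   threshold also gating this post-hoc test after Kruskal-Wallis).
#' @return Data.frame: `group1`, `group2`, `n1`, `n2`, `U`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
pairwise_mwu_bonferroni <- function(values, groups, alpha = 0.01) {
  lev <- sort(unique(groups))
  if (length(lev) < 2L)
    stop_value("pairwise_mwu_bonferroni: need >= 2 score groups")
  pairs <- cbind(lev[-length(lev)], lev[-1])
  m <- nrow(pairs)
  rows <- lapply(seq_len(m), function(i) {
    x <- values[groups == pairs[i, 1]]
    y <- values[groups == pairs[i, 2]]
    w <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    data.frame(group1 = pairs[i, 1], group2 = pairs[i, 2],
               n1 = length(x), n2 = length(y),
               U = unname(w$statistic), p = w$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$significant <- out$p < alpha / m
  rownames(out) <- NULL
  out
}

#' t-based 95% confidence interval
#'
#' `m +/- t_{0.025}(n-1) * s / sqrt(n)` with `m` the sample mean, `s` the
#' sample standard deviation (so `s / sqrt(n)` is the standard error) and
#' `t_{0.025}(n-1)` the upper 0.025 critical value of the t distribution
#' with n-1 degrees of freedom.
#'
#' @param samples Numeric vector, n >= 2.
#' @return List of class `"ci_result"`: `n`, `m`, `s`, `half_width`, `lo`,
#'   `hi`.
#' @export
t_confidence_interval <- function(samples) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 2L)
    stop_value("t_confidence_interval: need n >= 2 samples, got ", n)
  m <- mean(samples)
  s <- stats::sd(samples)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  structure(list(n = n, m = m, s = s, half_width = half,
                 lo = m - half, hi = m + half),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("mean %.4g, 95%% CI [%.4g, %.4g] (n = %d)\n",
              x$m, x$lo, x$hi, x$n))
  invisible(x)
}

#' Compare observed data against shuffled-score replicates
#'
#' Computes the observed Kruskal-Wallis p-value for average classifier
#' scores across combined human scores (TP and FN bouts pooled), the same
#' p-value within every shuffled replicate, and per-score recall for the
#' observed data versus the shuffled mean with a t-based 95% confidence
#' interval across replicates. A score's observed recall falling outside
#' that interval marks a score where the human-confidence / classifier
#' agreement departs from chance.
#'
#' Because the t interval is a confidence interval for the *mean* shuffled
#' recall (its width shrinks with the number of replicates), a single
#' observed value exchangeable with the replicates is not expected to fall
#' inside it 95% of the time; the empirical 2.5-97.5 percentile band of
#' the replicate recalls (`band_lo`, `band_hi`) is reported alongside as
#' the range of fluctuations a chance correlation would produce, and
#' `outside_band` is the corresponding flag.
#'
#' @param records Observed match records.
#' @param shuffles Replicates from [shuffle_scores()].
#' @return List of class `"null_report"`: `observed_p`, `shuffled_p`
#'   (vector), `observed_below_all` (logical), `recall_table` (data.frame
#'   with observed and shuffled-mean recall, t-CI bounds `lo`/`hi`,
#'   percentile band `band_lo`/`band_hi`, and `outside`/`outside_band`
#'   flags per score).
#' @export
null_comparison <- function(records, shuffles) {
  hb <- records$category %in% c("TP", "FN")
  if (!any(hb)) stop_value("null_comparison: no human-annotated bouts")
  obs <- kw_test(records$avg_classifier_score[hb], records$human_score[hb])
  shuf_p <- vapply(shuffles, function(s) {
    i <- s$category %in% c("TP", "FN")
    kw_test(s$avg_classifier_score[i], s$human_score[i])$p
  }, 0)
  obs_recall <- recall_by_score(records)
  shuf_recall <- lapply(shuffles, recall_by_score)
  scores <- sort(unique(as.integer(unlist(lapply(
    c(list(obs_recall), shuf_recall), names)))))
  tab <- lapply(scores, function(sc) {
    reps <- vapply(shuf_recall, function(r) {
      v <- r[as.character(sc)]
      if (is.na(v)) NA_real_ else as.numeric(v)
    }, 0)
    ci <- t_confidence_interval(reps)
    band <- stats::quantile(reps[!is.na(reps)], c(0.025, 0.975),
                            names = FALSE)
    o <- obs_recall[as.character(sc)]
    o <- if (is.na(o)) NA_real_ else as.numeric(o)
    data.frame(score = sc, observed = o, shuffled_mean = ci$m,
               lo = ci$lo, hi = ci$hi,
               band_lo = band[1], band_hi = band[2],
               outside = !is.na(o) & (o < ci$lo | o > ci$hi),
               outside_band = !is.na(o) &
                 (o < band[1] - 1e-12 | o > band[2] + 1e-12))
  })
  structure(list(observed_p = obs$p, observed_H = obs$H,
                 shuffled_p = shuf_p,
                 observed_below_all = obs$p < min(shuf_p),
                 recall_table = do.call(rbind, tab)),
            class = "null_report")
}

#' @export
print.null_report <- function(x, ...) {
  cat(sprintf("observed Kruskal-Wallis p = %.3g; %d shuffled p in [%.3g, %.3g]\n",
              x$observed_p, length(x$shuffled_p), min(x$shuffled_p),
              max(x$shuffled_p)))
  cat(if (x$observed_below_all)
    "observed p is below every shuffled replicate\n"
    else "observed p lies within the shuffled range\n")
  print(x$recall_table, row.names = FALSE)
  invisible(x)
}

#' Violin-style density summaries of classifier scores by human score
#'
#' Kernel density estimates (Scott's bandwidth rule, [stats::bw.nrd()]) of
#' average classifier scores for each combined human score 0-6, split into
#' TP and FN bouts (FPs are the score-0 group). The width scale of each
#' group is its bout count relative to the largest group, matching
#' count-scaled violin plots.
#'
#' @param records Match-record data.frame.
#' @return Data.frame, one row per (score, category) group: `n`, `scale`,
#'   `median`, plus a list-column `density` of `density` objects (NULL for
#'   groups with fewer than 2 distinct values).
#' @export
violin_summary <- function(records) {
  if (nrow(records) == 0L) stop_value("violin_summary: no records")
  key <- paste(records$human_score, records$category, sep = "/")
  groups <- split(records$avg_classifier_score, key)
  n <- vapply(groups, length, 0L)
  nmax <- max(n)
  parts <- strsplit(names(groups), "/", fixed = TRUE)
  out <- data.frame(
    human_score = as.integer(vapply(parts, `[[`, "", 1)),
    category = vapply(parts, `[[`, "", 2),
    n = as.integer(n),
    scale = as.numeric(n / nmax),
    median = vapply(groups, stats::median, 0),
    stringsAsFactors = FALSE)
  out$density <- lapply(groups, function(v) {
    if (length(unique(v)) < 2L) return(NULL)
    bw <- stats::bw.nrd(v)
    if (!is.finite(bw) || bw <= 0) return(NULL)
    stats::density(v, bw = bw)
  })
  out <- out[order(out$human_score, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
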