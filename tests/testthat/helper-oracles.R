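# Brute-force frame-enumeration oracles. These implement the interval
# operations literally on per-frame boolean/integer vectors, independently
# of the package's interval algebra, and random-instance generators for
# property tests.

make_bouts <- function(starts, ends, conf = 3L, movie = "m1", fly = "f1",
                       behavior = "lunge", observer = "obsA") {
  n <- length(starts)
  data.frame(movie_id = rep_len(movie, n), fly_id = rep_len(fly, n),
             behavior = rep_len(behavior, n),
             observer_id = rep_len(observer, n),
             start_frame = as.integer(starts),
             end_frame = as.integer(ends),
             confidence = rep_len(as.integer(conf), n),
             stringsAsFactors = FALSE)
}

# random internally non-overlapping bout set on [1, n_frames]
random_bout_set <- function(n_frames, max_bouts = 6L, observer = "obsA",
                            conf = NULL) {
  n <- sample(0:max_bouts, 1)
  if (n == 0L) return(make_bouts(integer(0), integer(0), integer(0),
                                 observer = observer))
  cuts <- sort(sample(seq_len(n_frames), min(2L * n, n_frames)))
  if (length(cuts) %% 2 == 1) cuts <- cuts[-length(cuts)]
  starts <- cuts[seq(1, length(cuts), by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- c(TRUE, starts[-1] > ends[-length(ends)])
  starts <- starts[keep]; ends <- ends[keep]
  conf <- conf %||% sample(1:3, length(starts), replace = TRUE)
  make_bouts(starts, ends, conf, observer = observer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# oracle: union-merge via frame painting + connected components of the
# painted union; returns extents sorted by start
bf_merge_extents <- function(bouts_a, bouts_b, n_frames) {
  covered <- logical(n_frames)
  for (df in list(bouts_a, bouts_b))
    for (i in seq_len(nrow(df)))
      covered[df$start_frame[i]:df$end_frame[i]] <- TRUE
  # components of covered frames, then merge components connected through
  # bouts that span a gap? Not possible: a bout covers its own frames, so
  # connectivity through overlap == connectivity of the covered mask only
  # when every pair of overlapping bouts shares a frame -- which is the
  # definition. Components of the mask can still join two non-overlapping
  # bouts that merely touch back-to-back (end+1 == start), which the
  # overlap rule keeps separate, so split mask components at boundaries
  # where no single bout spans the junction.
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  comp <- data.frame(start = starts[r$values], end = ends[r$values])
  out <- list()
  all_bouts <- rbind(bouts_a[, c("start_frame", "end_frame")],
                     bouts_b[, c("start_frame", "end_frame")])
  for (i in seq_len(nrow(comp))) {
    fr <- comp$start[i]:comp$end[i]
    # within a mask component, find overlap-connected components of bouts
    sub <- all_bouts[all_bouts$start_frame <= comp$end[i] &
                       all_bouts$end_frame >= comp$start[i], , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (p in seq_len(n)) for (q in seq_len(n)) {
      if (p < q && length(intersect(sub$start_frame[p]:sub$end_frame[p],
                                    sub$start_frame[q]:sub$end_frame[q]))
          > 0L) {
        rp <- find(p); rq <- find(q); if (rp != rq) parent[rq] <- rp
      }
    }
    roots <- vapply(seq_len(n), find, 0L)
    for (rt in unique(roots)) {
      grp <- sub[roots == rt, , drop = FALSE]
      out[[length(out) + 1L]] <- c(min(grp$start_frame), max(grp$end_frame))
    }
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start_frame = m[, 1], end_frame = m[, 2])
}

# oracle: literal three-step smoothing by frame enumeration
bf_detect <- function(scores, threshold, max_gap, min_len) {
  n <- length(scores)
  on <- scores > threshold
  if (max_gap > 0) {
    out <- on
    for (i in seq_len(n)) {
      if (on[i]) next
      # find the maximal off-run containing i
      lo <- i; while (lo > 1 && !on[lo - 1]) lo <- lo - 1
      hi <- i; while (hi < n && !on[hi + 1]) hi <- hi + 1
      if (lo > 1 && hi < n && (hi - lo + 1) <= max_gap) out[i] <- TRUE
    }
    on <- out
  }
  res <- NULL
  i <- 1
  while (i <= n) {
    if (on[i]) {
      j <- i
      while (j < n && on[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len)
        res <- rbind(res, data.frame(start_frame = i, end_frame = j,
                                     avg_score = mean(scores[i:j])))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(res))
    data.frame(start_frame = integer(0), end_frame = integer(0),
               avg_score = numeric(0))
  else res
}

# oracle: TP/FN/FP categories via frame-set intersection
bf_match_categories <- function(human, classifier, n_frames) {
  cmask <- logical(n_frames)
  for (i in seq_len(nrow(classifier)))
    cmask[classifier$start_frame[i]:classifier$end_frame[i]] <- TRUE
  hcat <- vapply(seq_len(nrow(human)), function(i)
    if (any(cmask[human$start_frame[i]:human$end_frame[i]])) "TP" else "FN",
    "")
  hmask <- logical(n_frames)
  for (i in seq_len(nrow(human)))
    hmask[human$start_frame[i]:human$end_frame[i]] <- TRUE
  fp <- vapply(seq_len(nrow(classifier)), function(i)
    !any(hmask[classifier$start_frame[i]:classifier$end_frame[i]]), TRUE)
  list(human_categories = hcat, n_fp = sum(fp))
}

# small uncoupled-null configuration shared by stats/acceptance tests.
# b1 = 0 removes the score-salience coupling; jitter_sd = 0 removes the
# residual correlation that boundary jitter would otherwise create (the
# union of two jittered copies makes two-observer bouts both higher-scored
# and slightly longer, hence more detectable), so the score assignment is
# exactly exchangeable under the null.
null_sim_config <- function(seed, n_frames = 9000L, prevalence = 6) {
  synthetic_config(
    seed = seed,
    movies = as_movies(data.frame(
      movie_id = "mm1", pair_type = "male_male", fps = 60,
      n_frames = as.integer(n_frames), role = "evaluation", wells = "")),
    behaviors = list(lunge = list(
      prevalence = c(male_male = prevalence, male_female = 0,
                     female_female = 0, other = 0),
      dur_median_frames = 4.5, dur_sigma = 0.25)),
    observer = list(a0 = 0.3, a1 = 2.6, conf_noise = 0.22,
                    cutpoints = c(0.35, 0.65), offsets = c(0, 0),
                    jitter_sd = 0, max_jitter = 2L),
    score = list(b0 = 0.05, b1 = 0, rho = 0.8, sigma = 0.03,
                 baseline = 0.005, distractor_rate = 0.15,
                 distractor_amp = 0.3, distractor_dur = 3L, clip = c(0, 1)))
}
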