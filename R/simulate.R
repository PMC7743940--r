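# Synthetic ethogram generator.
#
# Emulates the statistical structure the benchmarking pipeline assumes:
# ground-truth behavior bouts with a latent per-bout salience S ~ U(0,1)
# that drives BOTH how confidently human observers annotate a bout and how
# strongly the frame-wise classifier scores it -- encoding the view that
# variability in the behavior itself, not annotation noise alone, explains
# the human-confidence / classifier-confidence correlation. Two observers
# detect each truth bout with probability logistic(a0 + a1*S), grade it
# 1-3 by thresholding S plus observer noise, and jitter bout boundaries by
# a frame or two. Score tracks carry an on-bout level b0 + b1*S plus AR(1)
# noise, with a quiet baseline and occasional off-bout distractor bumps
# that create false-positive pressure. Setting b1 = 0 decouples classifier
# scores from salience, which is the null condition for permutation tests.

#' Synthetic dataset configuration
#'
#' Defaults emulate the annotated fly-pair movies at reduced scale: 60 fps
#' movies of male-male, male-female and female-female pairs; short
#' ballistic lunges and headbutts and heavy-tailed wing extensions, with
#' truth-duration medians (4.5 and 3.5 frames) set slightly below the
#' target annotated medians because the two-observer union widens a bout
#' by about one frame, so combined lunge bouts come out at a median of
#' 5 frames (83 ms) and headbutts at 4 frames (67 ms); behavior
#' prevalence concentrated in the sex combination where each behavior
#' occurs; observer parameters calibrated so roughly 30% of combined
#' bouts are seen by a single observer and about half carry a combined
#' score of 4-6.
#'
#' @param seed Integer master seed. Sub-streams for truth, each observer
#'   and the score tracks are derived from it (seed, seed+1, seed+2,
#'   seed+3), so regenerating one component leaves the others identical.
#' @param movies Data.frame (`movie_id`, `pair_type`, `fps`, `n_frames`,
#'   `role`) describing the movies to simulate; 2 flies per movie.
#' @param behaviors Named list, per behavior: `prevalence` (named
#'   bouts/minute/fly per pair type), `dur_median_frames`, `dur_sigma`
#'   (log-normal dispersion on the log scale).
#' @param observer List: `a0`, `a1` (logistic detection in salience),
#'   `conf_noise` (sd of Gaussian noise added to S before grading),
#'   `cutpoints` (two thresholds mapping S+noise to confidence 1/2/3),
#'   `offsets` (per-observer additive shifts, length 2 -- relative use of
#'   the confidence levels is discretionary to each observer),
#'   `jitter_sd` (boundary jitter sd, frames), `max_jitter` (hard clip).
#' @param score List: `b0`, `b1` (on-bout level b0 + b1*S; `b1 = 0` is the
#'   uncoupled null), `rho`, `sigma` (AR(1) autocorrelation and stationary
#'   sd), `baseline` (off-bout level), `distractor_rate` (bumps/minute),
#'   `distractor_amp`, `distractor_dur` (frames), `clip` (score range).
#' @param min_sep Minimum separation between truth bouts, frames.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    seed,
    movies = default_sim_movies(),
    behaviors = list(
      wing_extension = list(
        prevalence = c(male_male = 0.4, male_female = 3, female_female = 0,
                       other = 0.3),
        dur_median_frames = 30, dur_sigma = 1.0),
      lunge = list(
        prevalence = c(male_male = 3, male_female = 0, female_female = 0,
                       other = 0),
        dur_median_frames = 4.5, dur_sigma = 0.25),
      headbutt = list(
        prevalence = c(male_male = 0, male_female = 0, female_female = 3,
                       other = 0.2),
        dur_median_frames = 3.5, dur_sigma = 0.25)),
    observer = list(a0 = 0.3, a1 = 2.6, conf_noise = 0.22,
                    cutpoints = c(0.35, 0.65), offsets = c(0, 0),
                    jitter_sd = 0.6, max_jitter = 2L),
    score = list(b0 = 0.05, b1 = 0.6, rho = 0.8, sigma = 0.03,
                 baseline = 0.005, distractor_rate = 0.15,
                 distractor_amp = 0.3, distractor_dur = 3L,
                 clip = c(0, 1)),
    min_sep = 8L) {
  if (missing(seed) || is.null(seed))
    stop_value("synthetic_config: seed is required")
  movies <- as_movies(movies)
  for (beh in names(behaviors)) {
    b <- behaviors[[beh]]
    if (any(b$prevalence < 0) || b$dur_median_frames < 1 || b$dur_sigma < 0)
      stop_value("synthetic_config: invalid parameters for ", beh)
    # feasibility: expected occupied frames must leave room on every track
    mean_dur <- b$dur_median_frames * exp(b$dur_sigma^2 / 2)
    for (i in seq_len(nrow(movies))) {
      prev <- b$prevalence[[movies$pair_type[i]]]
      minutes <- movies$n_frames[i] / movies$fps[i] / 60
      expected <- prev * minutes * (mean_dur + min_sep)
      if (expected > 0.5 * movies$n_frames[i])
        stop_value("synthetic_config: infeasible -- expected ", beh,
                   " bouts would occupy most of movie '",
                   movies$movie_id[i], "'")
    }
  }
  if (score$rho < 0 || score$rho >= 1)
    stop_value("synthetic_config: score$rho must be in [0, 1)")
  if (observer$a1 < 0 || score$b1 < 0)
    stop_value("synthetic_config: coupling parameters a1, b1 must be >= 0")
  structure(list(seed = as.integer(seed), movies = movies,
                 behaviors = behaviors, observer = observer, score = score,
                 min_sep = as.integer(min_sep)),
            class = "synthetic_config")
}

#' Default simulated movie inventory
#'
#' Six 5-minute evaluation movies at 60 fps: two male-male, two
#' male-female, two female-female pairs.
#' @param n_frames Frames per movie.
#' @return Movie metadata data.frame.
#' @export
default_sim_movies <- function(n_frames = 18000L) {
  as_movies(data.frame(
    movie_id = sprintf("sim_%s_%d", rep(c("mm", "mf", "ff"), each = 2), 1:2),
    pair_type = rep(c("male_male", "male_female", "female_female"), each = 2),
    fps = 60, n_frames = as.integer(n_frames), role = "evaluation",
    wells = "", stringsAsFactors = FALSE))
}

# place n non-overlapping bouts of durations d on [1, n_frames] with gaps
# >= min_sep, uniformly over feasible arrangements
place_bouts <- function(d, n_frames, min_sep) {
  n <- length(d)
  if (n == 0L) return(integer(0))
  free <- n_frames - sum(d) - (n - 1L) * min_sep - 2L
  if (free < 0)
    stop_value("synthetic generator: sampled bouts do not fit in the track",
               " (infeasible prevalence/duration configuration)")
  cuts <- sort(stats::runif(n, 0, free))
  gaps <- floor(cuts)
  starts <- 2L + gaps + c(0L, cumsum(d[-n] + min_sep))
  as.integer(starts)
}

#' Generate ground-truth bouts
#'
#' @param config [synthetic_config()]. Uses the truth RNG stream
#'   (`config$seed`).
#' @return Data.frame: `movie_id`, `fly_id`, `behavior`, `start_frame`,
#'   `end_frame`, `salience`.
#' @export
generate_truth <- function(config) {
  set.seed(config$seed)
  mv <- config$movies
  rows <- list()
  for (i in seq_len(nrow(mv))) {
    minutes <- mv$n_frames[i] / mv$fps[i] / 60
    for (fly in c("fly1", "fly2")) {
      for (beh in names(config$behaviors)) {
        b <- config$behaviors[[beh]]
        prev <- b$prevalence[[mv$pair_type[i]]]
        n <- stats::rpois(1, prev * minutes)
        if (n == 0L) next
        d <- pmax(1L, as.integer(round(stats::rlnorm(
          n, log(b$dur_median_frames), b$dur_sigma))))
        starts <- place_bouts(d, mv$n_frames[i], config$min_sep)
        rows[[length(rows) + 1L]] <- data.frame(
          movie_id = mv$movie_id[i], fly_id = fly, behavior = beh,
          start_frame = starts, end_frame = starts + d - 1L,
          salience = stats::runif(n), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(movie_id = character(0), fly_id = character(0),
                      behavior = character(0), start_frame = integer(0),
                      end_frame = integer(0), salience = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate one observer's annotations from truth bouts
#'
#' Detection probability `plogis(a0 + a1 * S)`; confidence = 1 + number of
#' cutpoints below `S + noise + offset`; boundary jitter is clipped to
#' `max_jitter` frames (below half the truth-bout separation, so observer
#' bouts never overlap) and always leaves the bout overlapping its
#' generating truth bout.
#'
#' @param truth Output of [generate_truth()].
#' @param observer Observer parameter list (see [synthetic_config()]).
#' @param seed RNG seed for this observer's stream.
#' @param observer_id Label for the output.
#' @param which_observer 1 or 2 (selects the offset).
#' @param movies Movie metadata (for frame-range clipping).
#' @return Observer-bout data.frame in the [read_annotations()] schema plus
#'   a `truth_index` provenance column.
#' @export
generate_observer_annotations <- function(truth, observer, seed, observer_id,
                                          which_observer = 1L, movies) {
  set.seed(as.integer(seed))
  n <- nrow(truth)
  empty <- data.frame(movie_id = character(0), fly_id = character(0),
                      behavior = character(0), observer_id = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      confidence = integer(0), truth_index = integer(0))
  if (n == 0L) return(empty)
  p <- stats::plogis(observer$a0 + observer$a1 * truth$salience)
  detected <- stats::runif(n) < p
  v <- truth$salience + stats::rnorm(n, 0, observer$conf_noise) +
    observer$offsets[which_observer]
  conf <- 1L + (v > observer$cutpoints[1]) + (v > observer$cutpoints[2])
  mj <- observer$max_jitter
  js <- pmax(-mj, pmin(mj, round(stats::rnorm(n, 0, observer$jitter_sd))))
  je <- pmax(-mj, pmin(mj, round(stats::rnorm(n, 0, observer$jitter_sd))))
  s <- truth$start_frame + as.integer(js)
  e <- truth$end_frame + as.integer(je)
  # keep valid and overlapping the generating bout
  s <- pmin(s, truth$end_frame)
  e <- pmax(e, truth$start_frame)
  bad <- s > e
  s[bad] <- truth$start_frame[bad]
  e[bad] <- truth$end_frame[bad]
  nf <- movies$n_frames[match(truth$movie_id, movies$movie_id)]
  s <- pmax(1L, s)
  e <- pmin(nf, e)
  out <- data.frame(
    movie_id = truth$movie_id, fly_id = truth$fly_id,
    behavior = truth$behavior, observer_id = observer_id,
    start_frame = as.integer(s), end_frame = as.integer(e),
    confidence = as.integer(conf), truth_index = seq_len(n),
    stringsAsFactors = FALSE)[detected, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a classifier score track for one (movie, fly, behavior)
#'
#' On-bout level `b0 + b1 * S`, off-bout baseline, optional distractor
#' bumps, all overlaid with stationary AR(1) noise and clipped to the
#' score range. Assumes the RNG state is already positioned (called from
#' [generate_dataset()] inside the score stream); seed with `set.seed()`
#' when calling directly.
#'
#' @param truth_bouts Truth bouts for this track (may have zero rows).
#' @param n_frames Track length.
#' @param score Score parameter list (see [synthetic_config()]).
#' @param fps Frames per second (for the distractor rate).
#' @return Numeric score vector of length `n_frames`.
#' @export
generate_score_track <- function(truth_bouts, n_frames, score, fps = 60) {
  level <- rep(score$baseline, n_frames)
  for (i in seq_len(nrow(truth_bouts)))
    level[truth_bouts$start_frame[i]:truth_bouts$end_frame[i]] <-
      score$b0 + score$b1 * truth_bouts$salience[i]
  minutes <- n_frames / fps / 60
  m <- stats::rpois(1, score$distractor_rate * minutes)
  if (m > 0L) {
    ds <- sample.int(n_frames - score$distractor_dur, m, replace = TRUE)
    amp <- score$distractor_amp * stats::runif(m, 0.6, 1)
    for (k in seq_len(m)) {
      fr <- ds[k]:(ds[k] + score$distractor_dur - 1L)
      level[fr] <- pmax(level[fr], amp[k])
    }
  }
  innov <- stats::rnorm(n_frames, 0, score$sigma * sqrt(1 - score$rho^2))
  noise <- as.numeric(stats::filter(innov, score$rho, method = "recursive"))
  pmin(score$clip[2], pmax(score$clip[1], level + noise))
}

#' Generate a complete synthetic dataset
#'
#' Draws ground truth, two observers' graded annotations and per-frame
#' classifier score tracks for every (movie, fly, behavior), all
#' deterministically from `config$seed`.
#'
#' @param config [synthetic_config()].
#' @return List of class `"ethogram_sim"`: `movies`, `truth`,
#'   `annotations` (both observers, [read_annotations()] schema +
#'   `truth_index`), `tracks` ([as_score_tracks()] shape), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- generate_truth(config)
  obs_a <- generate_observer_annotations(truth, config$observer,
                                         config$seed + 1L, "obsA", 1L,
                                         config$movies)
  obs_b <- generate_observer_annotations(truth, config$observer,
                                         config$seed + 2L, "obsB", 2L,
                                         config$movies)
  annotations <- rbind(obs_a, obs_b)
  set.seed(config$seed + 3L)
  mv <- config$movies
  grid <- expand.grid(fly_id = c("fly1", "fly2"),
                      movie_id = mv$movie_id,
                      behavior = names(config$behaviors),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$movie_id, grid$fly_id, grid$behavior), ,
               drop = FALSE]
  scores <- lapply(seq_len(nrow(grid)), function(i) {
    nf <- mv$n_frames[match(grid$movie_id[i], mv$movie_id)]
    fps <- mv$fps[match(grid$movie_id[i], mv$movie_id)]
    tb <- truth[truth$movie_id == grid$movie_id[i] &
                  truth$fly_id == grid$fly_id[i] &
                  truth$behavior == grid$behavior[i], , drop = FALSE]
    generate_score_track(tb, nf, config$score, fps)
  })
  tracks <- data.frame(movie_id = grid$movie_id, fly_id = grid$fly_id,
                       behavior = grid$behavior,
                       n_frames = mv$n_frames[match(grid$movie_id,
                                                    mv$movie_id)],
                       stringsAsFactors = FALSE)
  tracks$scores <- scores
  rownames(tracks) <- NULL
  structure(list(movies = mv, truth = truth, annotations = annotations,
                 tracks = tracks, config = config),
            class = "ethogram_sim")
}

#' @export
print.ethogram_sim <- function(x, ...) {
  cat(sprintf("synthetic ethogram: %d movies, %d truth bouts, %d observer bouts, %d score tracks (seed %d)\n",
              nrow(x$movies), nrow(x$truth), nrow(x$annotations),
              nrow(x$tracks), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to CSV files
#'
#' Emits `movies.csv`, `annotations.csv`, `scores.csv` (long format) and
#' `truth.csv` in the package's I/O schemas. Byte-identical for identical
#' configs.
#'
#' @param sim Output of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("movies.csv", "annotations.csv", "scores.csv",
                            "truth.csv"))
  write_table(sim$movies, paths[1])
  ann <- sim$annotations[, ANNOTATION_COLS]
  write_table(ann, paths[2])
  write_table(tracks_to_long(sim$tracks), paths[3])
  write_table(sim$truth, paths[4])
  invisible(paths)
}

#' The 13 per-frame tracker features
#'
#' Names of the 13 basic pose/motion features computed per fly per frame
#' by the tracker, with the 4 "relative" features (computed from the
#' relative positions of the two flies) flagged.
#'
#' @return Data.frame: `feature`, `relative`.
#' @export
flytracker_features <- function() {
  data.frame(
    feature = c("log_max_wing_ang", "facing_angle", "norm_mean_wing_length",
                "log_min_wing_ang", "dist_to_wall", "norm_axis_ratio",
                "log_fg_body_ratio", "leg_dist", "log_vel", "dist_to_other",
                "log_ang_vel", "norm_contrast", "angle_between"),
    relative = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                 FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate a per-frame feature table
#'
#' Standard-normal feature values with a per-feature mean shift on
#' annotated frames -- enough structure to exercise the z-score profiling,
#' without pretending to model fly kinematics.
#'
#' @param annotated Logical vector (one per frame) marking annotated frames.
#' @param seed RNG seed.
#' @param shift Mean shift applied on annotated frames (recycled across
#'   the 13 features).
#' @return Data.frame with `frame` plus the 13 feature columns.
#' @export
simulate_features <- function(annotated, seed, shift = 1) {
  set.seed(as.integer(seed))
  feats <- flytracker_features()$feature
  shift <- rep_len(shift, length(feats))
  out <- data.frame(frame = seq_along(annotated))
  for (i in seq_along(feats))
    out[[feats[i]]] <- stats::rnorm(length(annotated)) +
      ifelse(annotated, shift[i], 0)
  out
}
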