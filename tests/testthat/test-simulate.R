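small_movies <- function(n_frames = 6000L, types = c("MM", "MF", "FF")) {
  as_movies(data.frame(
    movie_id = paste0("m", seq_along(types)), pair_type = types,
    fps = 60, n_frames = as.integer(n_frames), role = "evaluation"))
}

test_that("identical configs generate byte-identical datasets", {
  cfg <- synthetic_config(seed = 17, movies = small_movies())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in c("movies.csv", "annotations.csv", "scores.csv", "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_dataset(generate_dataset(synthetic_config(seed = 18,
                                                  movies = small_movies())),
                d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "truth.csv"))),
                         unname(tools::md5sum(file.path(d3, "truth.csv")))))
})

test_that("zero prevalence gives empty annotations and pure-noise tracks", {
  cfg <- synthetic_config(
    seed = 2, movies = small_movies(types = "MM"),
    behaviors = list(lunge = list(
      prevalence = c(male_male = 0, male_female = 0, female_female = 0,
                     other = 0),
      dur_median_frames = 4.5, dur_sigma = 0.25)))
  sim <- generate_dataset(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(sim$annotations), 0L)
  expect_equal(nrow(sim$tracks), 2L)
  expect_true(all(unlist(sim$tracks$scores) < 0.3))
})

test_that("sampled durations reproduce the configured medians", {
  # a lunge-like duration model with median 5 frames: over 10k bouts the
  # empirical median is 83 ms at 60 fps (within one frame)
  set.seed(77)
  d <- pmax(1L, as.integer(round(stats::rlnorm(10000, log(5), 0.25))))
  med_ms <- stats::median(d) * 1000 / 60
  expect_lte(abs(med_ms - 83.3), 1000 / 60)
  # generator truth bouts follow the configured model at scale
  cfg <- synthetic_config(seed = 5, movies = small_movies(60000L, "MM"),
                          behaviors = list(lunge = list(
                            prevalence = c(male_male = 10, male_female = 0,
                                           female_female = 0, other = 0),
                            dur_median_frames = 5, dur_sigma = 0.25)))
  truth <- generate_truth(cfg)
  expect_gt(nrow(truth), 100)
  expect_equal(stats::median(truth$end_frame - truth$start_frame + 1L), 5)
  # truth bouts never overlap and respect the separation
  by_track <- split(truth, paste(truth$movie_id, truth$fly_id))
  for (g in by_track) {
    g <- g[order(g$start_frame), ]
    if (nrow(g) > 1L)
      expect_true(all(g$start_frame[-1] - g$end_frame[-nrow(g)] >
                        cfg$min_sep))
  }
})

test_that("infeasible prevalence/duration combinations are rejected", {
  expect_error(synthetic_config(
    seed = 1, movies = small_movies(600L, "MM"),
    behaviors = list(lunge = list(
      prevalence = c(male_male = 600, male_female = 0, female_female = 0,
                     other = 0),
      dur_median_frames = 30, dur_sigma = 0.25))), "infeasible")
})

test_that("observer model hits detection, grading and jitter contracts", {
  mv <- small_movies(200000L, "MM")
  truth <- data.frame(
    movie_id = "m1", fly_id = "f1", behavior = "lunge",
    start_frame = seq(10L, 199000L, by = 20L))
  truth$end_frame <- truth$start_frame + 4L
  truth$salience <- stats::runif(nrow(truth))
  # near-step detection at S = 0.5: bouts below the (narrow) logistic
  # transition are never annotated
  step <- list(a0 = -300, a1 = 600, conf_noise = 0, cutpoints = c(.35, .65),
               offsets = c(0, 0), jitter_sd = 0, max_jitter = 2L)
  ann <- generate_observer_annotations(truth, step, 1, "obsA", 1L, mv)
  expect_true(all(truth$salience[ann$truth_index] > 0.5 - 10 / 600))
  expect_gt(nrow(ann), 0L)
  # perfect observers: exact truth extents, one-observer fraction 0
  perfect <- list(a0 = 1000, a1 = 0, conf_noise = 0, cutpoints = c(.35, .65),
                  offsets = c(0, 0), jitter_sd = 0, max_jitter = 2L)
  a <- generate_observer_annotations(truth, perfect, 2, "obsA", 1L, mv)
  b <- generate_observer_annotations(truth, perfect, 3, "obsB", 2L, mv)
  expect_equal(a$start_frame, truth$start_frame)
  expect_equal(a$end_frame, truth$end_frame)
  comb <- combine_annotations(rbind(a, b))
  expect_equal(mean(comb$observer_count == 1L), 0)
  # every observer bout overlaps its generating truth bout
  cfg <- synthetic_config(seed = 23, movies = small_movies())
  sim <- generate_dataset(cfg)
  ov <- sim$annotations$start_frame <=
    sim$truth$end_frame[sim$annotations$truth_index] &
    sim$annotations$end_frame >=
    sim$truth$start_frame[sim$annotations$truth_index]
  expect_true(all(ov))
})

test_that("calibrated defaults reproduce the single-observer band", {
  # large sample: single-observer fraction within +/- 3 points of 30%
  mv <- small_movies(600000L)
  cfg <- synthetic_config(seed = 29, movies = mv)
  truth <- generate_truth(cfg)
  a <- generate_observer_annotations(truth, cfg$observer, cfg$seed + 1L,
                                     "obsA", 1L, mv)
  b <- generate_observer_annotations(truth, cfg$observer, cfg$seed + 2L,
                                     "obsB", 2L, mv)
  comb <- combine_annotations(rbind(a, b))
  recs <- score_record_table(comb)
  expect_gt(nrow(recs), 2000)
  expect_lt(abs(mean(recs$observer_count == 1L) - 0.30), 0.03)
})

test_that("score-salience coupling controls the per-bout correlation", {
  mv <- small_movies(200000L, "MM")
  truth <- data.frame(
    movie_id = "m1", fly_id = "f1", behavior = "lunge",
    start_frame = seq(10L, 199000L, by = 20L))
  truth$end_frame <- truth$start_frame + 4L
  truth$salience <- stats::runif(nrow(truth))
  base <- list(b0 = 0.05, b1 = 0.6, rho = 0.8, sigma = 0.03,
               baseline = 0.005, distractor_rate = 0, distractor_amp = 0,
               distractor_dur = 1L, clip = c(0, 1))
  bout_means <- function(scores)
    vapply(seq_len(nrow(truth)), function(i)
      mean(scores[truth$start_frame[i]:truth$end_frame[i]]), 0)
  set.seed(101)
  s_cpl <- generate_score_track(truth, 200000L, base, fps = 60)
  rho_cpl <- stats::cor(bout_means(s_cpl), truth$salience,
                        method = "spearman")
  expect_gt(rho_cpl, 0.8)
  un <- base; un$b1 <- 0
  set.seed(102)
  s_un <- generate_score_track(truth, 200000L, un, fps = 60)
  expect_lt(abs(stats::cor(bout_means(s_un), truth$salience,
                           method = "spearman")), 0.05)
  # no distractors and a baseline far below threshold: zero false positives
  quiet <- base; quiet$sigma <- 0.01
  set.seed(103)
  s_q <- generate_score_track(truth, 200000L, quiet, fps = 60)
  cb <- detect_bouts(s_q, smoothing_params(0.1, 1, 2))
  h <- data.frame(start_frame = truth$start_frame,
                  end_frame = truth$end_frame,
                  representative_score = 6L)
  m <- match_bouts(h, cb, s_q)
  expect_equal(sum(m$category == "FP"), 0L)
})
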