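fake_records <- function(categories, scores = NULL, avg = NULL,
                         movie = "m1") {
  n <- length(categories)
  data.frame(movie_id = movie, fly_id = "f1", behavior = "lunge",
             category = categories,
             human_score = as.integer(scores %||%
                                        ifelse(categories == "FP", 0L, 4L)),
             avg_classifier_score = avg %||% stats::runif(n),
             stringsAsFactors = FALSE)
}

test_that("precision and recall follow their defining ratios", {
  m <- precision_recall(fake_records(c(rep("TP", 9), "FP", rep("FN", 3))))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.75)
  # no classifier bouts: recall 0, precision undefined (a distinguished NA)
  m2 <- precision_recall(fake_records(rep("FN", 4)))
  expect_equal(m2$recall, 0)
  expect_true(is.na(m2$precision))
  # perfect matching
  m3 <- precision_recall(fake_records(rep("TP", 5)))
  expect_equal(m3$precision, 1)
  expect_equal(m3$recall, 1)
})

test_that("recall stratifies by human score, omitting absent scores", {
  r <- recall_by_score(fake_records(c("TP", "TP", "FN"),
                                    scores = c(6, 6, 3)))
  expect_equal(r, c("3" = 0, "6" = 1))
  r2 <- recall_by_score(fake_records(rep("TP", 4), scores = c(1, 1, 5, 5)))
  expect_equal(unname(r2), c(1, 1))
  # enumeration oracle on random fixtures
  set.seed(61)
  for (rep in 1:50) {
    cat <- sample(c("TP", "FN"), 40, replace = TRUE)
    sc <- sample(1:6, 40, replace = TRUE)
    rec <- fake_records(cat, scores = sc)
    got <- recall_by_score(rec)
    for (s in sort(unique(sc))) {
      expect_equal(unname(got[as.character(s)]),
                   sum(cat == "TP" & sc == s) / sum(sc == s))
    }
  }
})

test_that("overall recall is the count-weighted mean of per-score recall", {
  set.seed(62)
  rec <- fake_records(sample(c("TP", "FN"), 100, replace = TRUE),
                      scores = sample(1:6, 100, replace = TRUE))
  r <- recall_by_score(rec)
  n_s <- table(rec$human_score)
  expect_equal(unname(sum(r * n_s[names(r)]) / sum(n_s)),
               precision_recall(rec)$recall)
})

test_that("false-positive rates normalize by evaluated minutes per pair type",
{
  mv <- as_movies(data.frame(
    movie_id = c("a", "b", "c"), pair_type = c("MM", "MM", "FF"),
    fps = 60, n_frames = c(54000, 54000, 36000), role = "evaluation"))
  # 3 FP in 15 + 15 = 30 minutes of MM -> 0.1 per minute
  rec <- fake_records(rep("FP", 3), movie = c("a", "a", "b"))
  fr <- fp_rate_by_pair_type(rec, mv)
  expect_equal(fr$fp_per_min[fr$pair_type == "male_male"], 0.1)
  expect_equal(fr$fp_per_min[fr$pair_type == "female_female"], 0)
  # no FP at all: all-zero rates over types with nonzero time
  fr0 <- fp_rate_by_pair_type(fake_records("TP", movie = "a"), mv)
  expect_true(all(fr0$fp_per_min == 0))
  expect_setequal(fr0$pair_type, c("male_male", "female_female"))
})

test_that("grid search ranks by recall x precision with stable tie-breaks", {
  set.seed(63)
  sim <- generate_dataset(synthetic_config(
    seed = 63, movies = default_sim_movies(n_frames = 3000L)))
  comb <- combine_annotations(sim$annotations)
  tr <- sim$tracks[sim$tracks$behavior == "lunge", ]
  cb <- comb[comb$behavior == "lunge", ]
  g1 <- parameter_grid_search(cb, tr, thresholds = 0.1, max_gaps = 1,
                              min_bout_lens = 2)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$rank, 1L)
  # 2x2x2 grid equals brute-force evaluation of all 8 points
  g <- parameter_grid_search(cb, tr, thresholds = c(0.1, 0.5),
                             max_gaps = c(0, 2), min_bout_lens = c(1, 3))
  expect_equal(nrow(g), 8L)
  for (i in seq_len(nrow(g))) {
    p <- smoothing_params(g$threshold[i], g$max_gap[i], g$min_bout_len[i])
    m <- precision_recall(match_all_bouts(cb, detect_all_bouts(tr, p), tr))
    expect_equal(g$recall_x_precision[i], m$recall_x_precision)
  }
  expect_true(all(diff(ifelse(is.na(g$recall_x_precision), -Inf,
                              g$recall_x_precision)) <= 0))
  # a threshold above every score kills all bouts -> undefined, ranked last
  g2 <- parameter_grid_search(cb, tr, thresholds = c(0.1, 2),
                              max_gaps = 1, min_bout_lens = 2)
  expect_true(is.na(g2$precision[g2$threshold == 2]))
  expect_equal(g2$rank[g2$threshold == 2], 2L)
})

test_that("feature z-scores standardize globally and split by label", {
  # hand-built six-frame table with a closed-form check
  feats <- data.frame(frame = 1:6, f1 = c(1, 2, 3, 4, 5, 6),
                      f2 = rep(2, 6))
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  prof <- feature_zscore_profiles(feats, lab, feature_cols = c("f1", "f2"))
  z <- (feats$f1 - mean(feats$f1)) / stats::sd(feats$f1)
  ann <- prof[prof$feature == "f1" & prof$group == "annotated", ]
  expect_equal(ann$median, stats::median(z[1:3]))
  expect_equal(ann$variance, stats::var(z[1:3]))
  expect_equal(ann$n, 3L)
  # constant feature flagged, not NaN-propagated
  f2 <- prof[prof$feature == "f2", ]
  expect_true(all(f2$zero_variance))
  expect_true(all(f2$variance == 0))
  # no annotated frames: a single unannotated group
  prof0 <- feature_zscore_profiles(feats, rep(FALSE, 6),
                                   feature_cols = "f1")
  expect_equal(unique(prof0$group), "unannotated")
  expect_equal(prof0$n, 6L)
  expect_error(feature_zscore_profiles(feats, lab[1:3]), "one entry")
})

test_that("simulated feature tables shift annotated frames as configured", {
  ann <- rep(c(TRUE, FALSE), c(300, 700))
  feats <- simulate_features(ann, seed = 9, shift = 2)
  expect_equal(ncol(feats), 14L)  # frame + 13 features
  expect_setequal(setdiff(names(feats), "frame"),
                  flytracker_features()$feature)
  expect_equal(sum(flytracker_features()$relative), 4L)
  prof <- feature_zscore_profiles(feats[, -1], ann)
  med_ann <- prof$median[prof$group == "annotated"]
  med_un <- prof$median[prof$group == "unannotated"]
  expect_true(all(med_ann > med_un))
})
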