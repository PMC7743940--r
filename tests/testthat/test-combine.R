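test_that("union merge applies the overlap, summation and split rules", {
  # simple two-observer overlap: extents union, confidences sum
  a <- make_bouts(100, 130, 3, observer = "obsA")
  b <- make_bouts(110, 140, 2, observer = "obsB")
  m <- merge_observer_bouts(a, b)
  expect_equal(m$start_frame, 100)
  expect_equal(m$end_frame, 140)
  expect_equal(m$score_records[[1]], 5L)
  expect_equal(m$observer_count, 2L)

  # split annotation: two A bouts inside one B bout -> two score records,
  # representative is the maximum
  a2 <- make_bouts(c(100, 120), c(110, 130), c(3, 2), observer = "obsA")
  b2 <- make_bouts(95, 135, 3, observer = "obsB")
  m2 <- merge_observer_bouts(a2, b2)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start_frame, m2$end_frame), c(95, 135))
  expect_equal(m2$score_records[[1]], c(6L, 5L))
  expect_equal(m2$representative_score, 6L)
  expect_equal(m2$n_records, 2L)

  # single-observer bout passes through unchanged
  m3 <- merge_observer_bouts(make_bouts(100, 110, 2), make_bouts(integer(0),
                                                                 integer(0)))
  expect_equal(c(m3$start_frame, m3$end_frame), c(100, 110))
  expect_equal(m3$score_records[[1]], 2L)
  expect_equal(m3$observer_count, 1L)

  # touching but non-overlapping bouts stay separate (overlap needs >= 1
  # shared frame)
  m4 <- merge_observer_bouts(make_bouts(10, 20, 1, observer = "obsA"),
                             make_bouts(21, 30, 1, observer = "obsB"))
  expect_equal(nrow(m4), 2L)
  expect_true(all(m4$observer_count == 1L))
})

test_that("merge is symmetric, conservative and idempotent under empties", {
  set.seed(11)
  empty <- make_bouts(integer(0), integer(0))
  for (rep in 1:50) {
    a <- random_bout_set(300, observer = "obsA")
    b <- random_bout_set(300, observer = "obsB")
    ab <- merge_observer_bouts(a, b)
    ba <- merge_observer_bouts(b, a)
    # symmetry: extents, record multisets, observer counts
    expect_equal(ab$start_frame, ba$start_frame)
    expect_equal(ab$end_frame, ba$end_frame)
    expect_equal(lapply(ab$score_records, sort),
                 lapply(ba$score_records, sort))
    expect_equal(ab$observer_count, ba$observer_count)
    # conservation: every input bout is covered by exactly one extent
    for (df in list(a, b)) for (i in seq_len(nrow(df))) {
      hits <- sum(ab$start_frame <= df$start_frame[i] &
                    ab$end_frame >= df$end_frame[i])
      expect_equal(hits, 1L)
    }
    # idempotence: merging with an empty observer preserves everything
    again <- merge_observer_bouts(
      data.frame(start_frame = ab$start_frame, end_frame = ab$end_frame,
                 confidence = ab$representative_score), empty)
    expect_equal(again$start_frame, ab$start_frame)
    expect_equal(again$end_frame, ab$end_frame)
    expect_equal(unlist(again$score_records) %||% integer(0),
                 ab$representative_score)
  }
})

test_that("merged extents equal brute-force overlap components", {
  set.seed(21)
  for (rep in 1:200) {
    nf <- sample(40:200, 1)
    a <- random_bout_set(nf, observer = "obsA")
    b <- random_bout_set(nf, observer = "obsB")
    got <- merge_observer_bouts(a, b)
    if (nrow(a) + nrow(b) == 0L) {
      expect_equal(nrow(got), 0L)
      next
    }
    oracle <- bf_merge_extents(a, b, nf)
    expect_equal(got$start_frame, oracle$start_frame)
    expect_equal(got$end_frame, oracle$end_frame)
  }
})

test_that("chained overlaps become one region via connected components", {
  a <- make_bouts(c(10, 30), c(20, 40), c(1, 2), observer = "obsA")
  b <- make_bouts(18, 32, 3, observer = "obsB")  # bridges A1 and A2
  m <- merge_observer_bouts(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start_frame, m$end_frame), c(10, 40))
  expect_equal(m$score_records[[1]], c(4L, 5L))
})

test_that("frame-wise combined scores sum the two observers per frame", {
  a <- make_bouts(100, 110, 3, observer = "obsA")
  b <- make_bouts(105, 115, 2, observer = "obsB")
  v <- frame_combined_scores(a, b, 200)
  expect_equal(unique(v[100:104]), 3L)
  expect_equal(unique(v[105:110]), 5L)
  expect_equal(unique(v[111:115]), 2L)
  expect_equal(sum(v[-(100:115)]), 0L)
  expect_equal(frame_combined_scores(a[0, ], b[0, ], 10), integer(10))
  expect_error(frame_combined_scores(a, b, 50), "exceeds n_frames")
})

test_that("a frame scores > 0 iff it lies inside a combined extent", {
  set.seed(31)
  for (rep in 1:40) {
    nf <- 150
    a <- random_bout_set(nf, observer = "obsA")
    b <- random_bout_set(nf, observer = "obsB")
    v <- frame_combined_scores(a, b, nf)
    m <- merge_observer_bouts(a, b)
    inside <- logical(nf)
    for (i in seq_len(nrow(m))) inside[m$start_frame[i]:m$end_frame[i]] <- TRUE
    expect_equal(v > 0L, inside)
  }
})

test_that("summaries count score records, grids and fractions correctly", {
  mv <- as_movies(data.frame(
    movie_id = c("m1", "m2"), pair_type = c("MM", "FF"),
    fps = 60, n_frames = 4000, role = "evaluation"))
  # constructed records: {5}, {2}, {6,3} -> 4 records, two of them 4-6,
  # one single-observer
  ann <- rbind(
    make_bouts(100, 130, 3, movie = "m1", observer = "obsA"),  # + B 2 -> 5
    make_bouts(110, 140, 2, movie = "m1", observer = "obsB"),
    make_bouts(300, 310, 2, movie = "m1", observer = "obsA"),  # alone -> 2
    make_bouts(c(500, 520), c(510, 530), c(3, 1), movie = "m2",
               observer = "obsA"),                              # {6, 4}
    make_bouts(495, 535, 3, movie = "m2", observer = "obsB"))
  comb <- combine_annotations(ann)
  s <- summarize_annotations(comb, mv)$lunge
  expect_equal(s$n_records, 4L)
  expect_equal(s$n_combined_bouts, 3L)
  expect_equal(s$frac_score_4_6, 3 / 4)   # records 5, 6, 4
  expect_equal(s$frac_one_observer, 1 / 4)
  expect_equal(sum(s$grid), s$n_records)
  expect_equal(s$grid["0", "0"], 0L)      # structurally empty cell
  expect_equal(s$grid["2", "0"], 1L)      # the single-observer record
  expect_equal(s$grid["3", "2"], 1L)
  expect_equal(as.integer(s$by_pair_type[c("male_male", "female_female")]),
               c(2L, 2L))
  # empty input -> all-zero summary
  s0 <- summarize_annotations(comb[0, ], mv)
  expect_length(s0, 0L)
})

test_that("durations convert frames to milliseconds at the movie rate", {
  d <- bout_duration_stats(data.frame(start_frame = 100, end_frame = 104),
                           fps = 60)
  expect_equal(d$durations_frames, 5L)
  expect_equal(d$median_ms, 83L)  # 5 frames at 16.67 ms
  d2 <- bout_duration_stats(data.frame(start_frame = 1, end_frame = 4), 60)
  expect_equal(d2$median_ms, 67L)
  expect_error(bout_duration_stats(data.frame(start_frame = integer(0),
                                              end_frame = integer(0))),
               "empty")
})

test_that("more than two observers per movie is rejected", {
  ann <- rbind(make_bouts(1, 5, 1, observer = "o1"),
               make_bouts(10, 15, 1, observer = "o2"),
               make_bouts(20, 25, 1, observer = "o3"))
  expect_error(combine_annotations(ann), "exactly two")
})
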