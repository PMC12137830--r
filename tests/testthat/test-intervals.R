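test_that("the distance filter keeps records at exactly the 12-inch bound", {
  recs <- mk_raw(rep("n001", 4), rep("n002", 4), 0:3, c(5, 11, 12, 74), 0L)
  out <- filter_min_distance(recs)
  expect_equal(out$distance_in, c(12L, 74L))
  expect_equal(nrow(filter_min_distance(raw_records())), 0L)
  expect_equal(filter_min_distance(recs, min_in = 0L), recs)
})

test_that("start/end matching follows the collation rules", {
  # direct match: start + end sharing (reporter, detectee, start time)
  iv <- pair_start_end(mk_raw(c("n001", "n001"), c("n002", "n002"),
                              c(0, 0), 74, c(0L, 195L)), quiet = TRUE)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$duration_s, 195L)
  # a lone start becomes the 10-second substitute interval
  iv <- pair_start_end(mk_raw("n001", "n002", 0, 74, 0L), quiet = TRUE)
  expect_equal(iv$duration_s, 10L)
  # orphan end records are retained at their stated duration (and logged)
  expect_message(
    iv <- pair_start_end(mk_raw("n001", "n002", 0, 74, 45L)),
    "no matching start")
  expect_equal(iv$duration_s, 45L)
  # exact duplicates are deduplicated; the largest duplicate end wins
  msgs <- capture_messages(
    iv <- pair_start_end(mk_raw(rep("n001", 4), rep("n002", 4), 0,
                                74, c(0L, 0L, 30L, 45L))))
  expect_true(any(grepl("duplicate", msgs)))
  expect_equal(iv$duration_s, 45L)
})

test_that("a collation of mixed start/end records reproduces the expected interval multiset", {
  # two matched pairs and one lone start, as in the collation illustration
  recs <- mk_raw(c("n001", "n001", "pr003", "pr003", "ss002"),
                 c("n002", "n002", "b007", "b007", "pr003"),
                 c(0, 0, 5, 5, 12), c(40, 40, 55, 55, 62),
                 c(0L, 195L, 0L, 30L, 0L))
  iv <- pair_start_end(recs, quiet = TRUE)
  got <- data.frame(rep = iv$reporter, t = as.numeric(iv$start_time) - as.numeric(T0),
                    dur = iv$duration_s)
  expect_equal(got[order(got$t), c("rep", "dur")],
               data.frame(rep = c("n001", "pr003", "ss002"),
                          dur = c(195L, 30L, 10L)),
               ignore_attr = TRUE)
  # matched durations are multiples of the 15-second processing cycle
  expect_true(all(iv$duration_s[iv$duration_s != 10L] %% 15L == 0L))
})

test_that("bidirectional union rewrites overlapping spans to min start / max end", {
  iv <- mk_iv(c("n001", "n002"), c("n002", "n001"), c(100, 97), c(60L, 58L))
  m <- merge_bidirectional(iv)
  expect_equal(nrow(m), 2L)
  expect_true(all(as.numeric(m$start_time) - as.numeric(T0) == 97))
  expect_true(all(m$duration_s == 63L))
  # a span with no counterpart gains a mirrored copy with an equal span
  m1 <- merge_bidirectional(mk_iv("n001", "b004", 0, 45L))
  expect_equal(nrow(m1), 2L)
  expect_setequal(m1$reporter, c("n001", "b004"))
  expect_equal(unique(m1$duration_s), 45L)
})

test_that("merging matches the literal pairwise-rewrite oracle on random sets", {
  set.seed(7)
  for (i in 1:60) {
    iv <- random_interval_set(n_badges = sample(3:8, 1),
                              n_iv = sample(5:50, 1),
                              span = sample(c(120, 600, 3000), 1))
    got <- normalize_intervals(merge_bidirectional(iv))
    want <- oracle_merge(iv)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("merged output is mirror-complete with identical spans", {
  set.seed(11)
  iv <- random_interval_set(n_badges = 6, n_iv = 40)
  m <- normalize_intervals(merge_bidirectional(iv))
  flipped <- data.frame(rep = m$det, det = m$rep, s = m$s, e = m$e, d = m$d)
  flipped <- flipped[order(flipped$rep, flipped$det, flipped$s), ]
  expect_equal(m, flipped, ignore_attr = TRUE)
})

test_that("build_intervals composes the stages deterministically", {
  # everything under 12 inches vanishes
  recs <- mk_raw(c("n001", "n001"), c("n002", "n002"), 0, 5, c(0L, 30L))
  expect_equal(nrow(build_intervals(recs, quiet = TRUE)), 0L)
  # a single matched pair yields one mirrored interval pair
  recs <- mk_raw(c("n001", "n001"), c("n002", "n002"), 0, 74, c(0L, 30L))
  iv <- build_intervals(recs, quiet = TRUE)
  expect_equal(nrow(iv), 2L)
  expect_true(all(iv$distance_in >= 12L))
  expect_identical(iv, build_intervals(recs, quiet = TRUE))
  # interval count never exceeds the filtered start-record count (plus
  # mirrors created by the union stage)
  set.seed(3)
  big <- random_interval_set(n_badges = 8, n_iv = 30)
  expect_lte(nrow(pair_start_end(filter_min_distance(
    mk_raw(big$reporter, big$detected,
           as.numeric(big$start_time) - as.numeric(T0),
           big$distance_in, 0L)), quiet = TRUE)),
    30L)
})
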