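test_that("scenario defaults echo the deployment constants", {
  sc <- sim_scenario()
  expect_equal(sc$rooms, 26L)
  expect_equal(sc$contact_threshold_in, 72)   # six feet
  expect_equal(sc$high_cycle_s, 15L)
  expect_equal(unname(sc$day_roster), c(12L, 19L, 12L))
  expect_equal(unname(sc$night_roster), c(6L, 15L, 8L))
  expect_equal(sc$shifts, 1:14)
  sh <- shift_spec(0)
  expect_equal(as.numeric(sh$end - sh$start, units = "hours"), 12)
  expect_equal(sh$kind, "day")
  expect_equal(format(sh$start, "%H:%M"), "07:00")
  expect_equal(shift_spec(3)$kind, "night")
  expect_error(sim_scenario(high_cycle_s = 14L))
})

test_that("layouts are deterministic with well-separated anchors", {
  sc1 <- sim_scenario(rooms = 1)
  lay1 <- generate_layout(sc1)
  expect_equal(nrow(lay1$placement), 4L)
  d <- as.matrix(dist(cbind(lay1$placement$x, lay1$placement$y))) / 10 * 12
  expect_true(all(d[upper.tri(d)] > 72))
  expect_identical(generate_layout(sim_scenario(seed = 3)) ,
                   generate_layout(sim_scenario(seed = 3)))
})

test_that("scripted stationary badges yield one true contact of the full duration", {
  # two badges 60 inches apart for 300 seconds
  times <- seq(0, 297, by = 3) + as.numeric(T0)
  x <- cbind(rep(0, 100), rep(5, 100))
  y <- cbind(rep(0, 100), rep(0, 100))
  tr <- badge_tracks(times, c("n001", "n002"), x, y)
  tc <- true_contacts(tr, threshold_in = 72)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$duration_s, 300)
  expect_equal(round(tc$min_distance_in), 60)
  # badges far apart never meet
  tr2 <- badge_tracks(times, c("n001", "n002"), cbind(rep(0, 100), rep(50, 100)), y)
  expect_equal(nrow(true_contacts(tr2, threshold_in = 72)), 0L)
})

test_that("a 300-second noiseless contact yields a matched pair with duration near truth", {
  sc <- noiseless_scenario()
  times <- seq(0, 897, by = 3) + as.numeric(T0)
  n <- length(times)
  # in range only for t in [120, 420)
  xb <- ifelse(times - as.numeric(T0) >= 120 & times - as.numeric(T0) < 420, 4, 40)
  tr <- badge_tracks(times, c("n001", "n002"), cbind(rep(0, n), xb), cbind(rep(0, n), rep(0, n)))
  rec <- sense_and_emit(tr, sc, clock_offsets = c(n001 = 0, n002 = 0))
  ends <- rec[rec$duration_s > 0, ]
  expect_equal(nrow(ends), 2L)  # one per sensing direction
  expect_true(all(ends$duration_s %% 15L == 0L))
  expect_true(all(ends$duration_s >= 285 & ends$duration_s <= 315))
})

test_that("a five-second contact leaves at most a lone start record", {
  sc <- noiseless_scenario()
  times <- seq(0, 297, by = 3) + as.numeric(T0)
  n <- length(times)
  xb <- ifelse(times - as.numeric(T0) >= 120 & times - as.numeric(T0) < 125, 4, 40)
  tr <- badge_tracks(times, c("n001", "n002"), cbind(rep(0, n), xb), cbind(rep(0, n), rep(0, n)))
  rec <- sense_and_emit(tr, sc, clock_offsets = c(n001 = 0, n002 = 0))
  expect_true(all(rec$duration_s == 0L))
  expect_lte(nrow(rec), 2L)
})

test_that("simulated raw streams are deterministic and format-faithful", {
  sc <- sim_scenario(seed = 9, rooms = 3,
                     day_roster = c(provider = 1L, nurse = 2L, support = 1L))
  s1 <- simulate_shift(sc, 2)
  s2 <- simulate_shift(sc, 2)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  p <- withr::local_tempfile(fileext = ".json.xz")
  write_records(s1$records, p)
  back <- parse_raw_records(p)   # strict parse: labels, datetimes, fields
  expect_equal(nrow(back), nrow(s1$records))
  expect_equal(back$reporter, s1$records$reporter)
  expect_equal(back$duration_s, s1$records$duration_s)
})

test_that("raising the contact threshold never loses true contacts", {
  sc <- noiseless_scenario(seed = 13)
  lay <- generate_layout(sc)
  sh <- shift_spec(2, sc$first_day)
  tr <- simulate_movement(sc, lay, sh)
  idx <- seq_len(1200)
  tr1 <- badge_tracks(tr$times[idx], tr$badges, tr$x[idx, ], tr$y[idx, ])
  sm <- micutrace:::pair_samples(tr1, lay$placement, max_in = 90,
                                 min_hcp_in = sc$mobility$body_min_in)
  t60 <- true_contacts(tr1, lay$placement, 60, samples = sm)
  t72 <- true_contacts(tr1, lay$placement, 72, samples = sm)
  expect_gte(sum(t72$duration_s), sum(t60$duration_s))
  expect_gte(nrow(t72), 0L)
  # every sub-threshold second at 60 in is also sub-threshold at 72 in
  expect_true(all(t60$min_distance_in <= 60))
})

test_that("receptacle artifacts emit sub-12-inch records that the filter removes", {
  sc <- sim_scenario(seed = 21, rooms = 2,
                     day_roster = c(provider = 1L, nurse = 1L, support = 1L),
                     receptacle_artifacts = TRUE, extra_badges = 3L)
  sim <- simulate_shift(sc, 2)
  expect_true(any(sim$records$distance_in < 12L))
  iv <- build_intervals(sim$records, quiet = TRUE)
  expect_true(all(iv$distance_in >= 12L))
  # the unworn extra badges only ever appear below the filter distance
  extra <- setdiff(unique(sim$records$reporter), c(sim$tracks$badges,
                                                   sim$placement$anchor))
  expect_gte(length(extra), 1L)
  expect_false(any(c(iv$reporter, iv$detected) %in% extra))
})
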