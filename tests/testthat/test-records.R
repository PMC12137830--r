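test_that("badge roles follow the label prefix and reject unknown prefixes", {
  expect_equal(role_of(c("b097", "n008", "pr015", "ss044")),
               c("anchor", "nurse", "provider", "support"))
  expect_error(role_of("x001"), "invalid badge label")
  expect_error(role_of("nurse8"), "invalid badge label")
  # property: total on valid labels, error on everything else
  set.seed(42)
  for (i in 1:50) {
    idx <- sample.int(999, 1)
    role <- sample(c("anchor", "provider", "nurse", "support"), 1)
    expect_equal(role_of(badge_label(role, idx)), role)
    junk <- paste0(sample(c("q", "z", "bb", "sn", "B", ""), 1), idx)
    expect_error(role_of(junk))
  }
})

test_that("datetime strings parse liberally and format canonically", {
  t <- parse_badge_datetime("datetime(2023,4,25,7,39,43)")
  expect_equal(format(t, "%Y-%m-%d %H:%M:%S"), "2023-04-25 07:39:43")
  # quotes and spaces tolerated on input
  expect_equal(parse_badge_datetime('"datetime(2023, 4, 25, 7, 39, 43)"'), t)
  expect_equal(format_badge_datetime(t), "datetime(2023,4,25,7,39,43)")
  expect_error(parse_badge_datetime("2023-04-25 07:39:43"), "unparseable")
})

test_that("the documented example record parses to its printed field values", {
  r <- parse_raw_records(
    text = '[["pr014","pr037","datetime(2023,4,25,7,39,43)",74,0]]')
  expect_equal(nrow(r), 1L)
  expect_equal(r$reporter, "pr014")
  expect_equal(r$detected, "pr037")
  expect_equal(format_badge_datetime(r$start_time), "datetime(2023,4,25,7,39,43)")
  expect_equal(r$distance_in, 74L)
  expect_equal(r$duration_s, 0L)  # zero duration marks the start of contact
})

test_that("records round-trip through write/parse, compressed and not", {
  recs <- mk_raw(c("pr014", "pr014", "n002"), c("pr037", "pr037", "b005"),
                 c(0, 0, 30), c(74, 74, 20), c(0, 195, 0))
  for (ext in c(".json", ".json.xz")) {
    p <- withr::local_tempfile(fileext = ext)
    write_records(recs, p)
    back <- parse_raw_records(p)
    expect_equal(unclass(back), unclass(recs), ignore_attr = TRUE)
  }
  # empty list round-trips as []
  p <- withr::local_tempfile(fileext = ".json")
  write_records(raw_records(), p)
  expect_identical(readLines(p), "[]")
  expect_equal(nrow(parse_raw_records(p)), 0L)
})

test_that("an interval file preserves the 10-second substitute duration", {
  iv <- mk_iv("n001", "b002", 0, 10L)
  p <- withr::local_tempfile(fileext = ".json")
  write_records(iv, p)
  expect_match(paste(readLines(p), collapse = ""), ", 10]")
  expect_equal(read_intervals(p)$duration_s, 10L)
})

test_that("malformed records report their index; lenient mode skips them", {
  bad <- '[["pr014","pr037","datetime(2023,4,25,7,39,43)",74,0],["x001","n002","datetime(2023,4,25,8,0,0)",30,0]]'
  expect_error(parse_raw_records(text = bad), "record 2")
  expect_equal(nrow(suppressMessages(
    parse_raw_records(text = bad, lenient = TRUE))), 1L)
  expect_error(parse_raw_records(text = '[["n001","n002","notatime",3,0]]'),
               "unparseable")
  expect_error(parse_raw_records(text = '[["n001","n002"]]'), "5 fields")
})

test_that("contact intervals reject non-positive durations at construction", {
  expect_error(contact_intervals("n001", "n002", T0, 40L, 0L),
               "positive duration")
  expect_error(parse_raw_records(text = '[["n001","n002","datetime(2023,4,25,8,0,0)",30,0]]',
                                 intervals = TRUE),
               "positive duration")
  expect_silent(contact_intervals("n001", "n002", T0, 40L, 15L))
})

test_that("placement files validate rooms, stations and anchor separation", {
  sc <- sim_scenario(rooms = 3)
  lay <- generate_layout(sc)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_placement(lay$placement, p)
  back <- load_placement(p)
  expect_equal(nrow(back), 12L)  # 3 rooms x 4 stations
  expect_equal(back$anchor, lay$placement$anchor)
  expect_equal(back$station, lay$placement$station)
  expect_equal(back$x, lay$placement$x)
  # two anchors at identical coordinates violate the six-feet rule
  bad <- lay$placement
  bad$x[2] <- bad$x[1]; bad$y[2] <- bad$y[1]
  expect_error(validate_placement(bad), "six feet")
  # a room missing a station type is rejected
  expect_error(anchor_placement(lay$placement$anchor[-2],
                                lay$placement$room[-2],
                                lay$placement$station[-2],
                                lay$placement$x[-2], lay$placement$y[-2]),
               "station type")
  expect_error(anchor_placement("n001", 1, "door", 0, 0), "non-anchor")
})

test_that("the default unit layout has 26 rooms with 4 anchors each", {
  lay <- generate_layout(sim_scenario())
  pl <- lay$placement
  expect_equal(nrow(pl), 104L)
  expect_equal(length(unique(pl$room)), 26L)
  expect_true(all(table(pl$room) == 4L))
  expect_silent(validate_placement(pl))
})
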