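test_that("imputation omits anchors as keys yet keeps them in contact lists", {
  # an anchor b in contact with HCPs a and c; d-e contact persists longer
  sh <- shift_spec(2)
  iv <- mk_iv(c("n001", "pr003", "ss004"),
              c("b002", "b002", "n005"),
              c(10, 10, 10), c(10L, 10L, 20L))
  h <- impute_history(iv, sh, quiet = TRUE)
  at <- history_at(h, T0 + 14)
  expect_false("b002" %in% names(at))
  expect_equal(at$n001$contacts, "b002")
  expect_equal(at$pr003$contacts, "b002")
  # at a later second only the HCP pair remains, in both directions
  at23 <- history_at(h, T0 + 23)
  expect_setequal(names(at23), c("ss004", "n005"))
  expect_equal(at23$ss004$contacts, "n005")
  expect_equal(at23$n005$contacts, "ss004")
  # no intervals -> empty maps everywhere
  h0 <- impute_history(contact_intervals(), sh, quiet = TRUE)
  expect_length(history_at(h0, T0 + 1), 0L)
})

test_that("anchor-to-anchor intervals are logged and excluded", {
  iv <- mk_iv(c("b001", "n001"), c("b002", "b002"), c(0, 0), c(30L, 30L))
  expect_message(h <- impute_history(iv, shift_spec(2)), "anchor-to-anchor")
  expect_equal(unique(h$contacts$badge), "n001")
})

test_that("imputation matches the per-second expansion oracle on random sets", {
  set.seed(19)
  sh <- shift_spec(2)
  for (i in 1:40) {
    iv <- random_interval_set(n_badges = sample(4:10, 1),
                              n_iv = sample(5:30, 1),
                              span = sample(c(200, 1000), 1))
    h <- impute_history(iv, sh, quiet = TRUE)
    expect_equal(history_triples(h), oracle_impute_triples(iv, sh),
                 ignore_attr = TRUE)
  }
})

test_that("history symmetry holds between HCP badges", {
  set.seed(23)
  iv <- random_interval_set(n_badges = 8, n_iv = 30, span = 400)
  h <- impute_history(iv, shift_spec(2), quiet = TRUE)
  tri <- history_triples(h)
  hcp <- tri[!is_anchor(tri$contact), ]
  swapped <- data.frame(t = hcp$t, badge = hcp$contact, contact = hcp$badge)
  expect_equal(nrow(merge(hcp, swapped)), nrow(hcp))
  expect_false(any(is_anchor(h$contacts$badge)))
})

placement3 <- generate_layout(sim_scenario(rooms = 3, common_anchors = 1))$placement
# room r anchors: door b(4r-3), sink b(4r-2), computer b(4r-1), vitals b(4r)

test_that("in-room state sets on interior anchors and survives same-room contacts", {
  sh <- shift_spec(2)
  iv <- mk_iv(c("n001", "n001"), c("b008", "b006"), c(100, 300), c(60L, 60L))
  # vitals of room 2 at t=100, then sink of room 2 at t=300
  h <- annotate_inroom(impute_history(iv, sh, quiet = TRUE), placement3,
                       quiet = TRUE)
  expect_null(state_room(h, "n001", T0 + 50))
  expect_equal(state_room(h, "n001", T0 + 120), 2L)
  expect_equal(state_room(h, "n001", T0 + 250), 2L)  # persists between contacts
  expect_equal(state_room(h, "n001", T0 + 350), 2L)
  expect_equal(state_room(h, "n001", T0 + 3600), 2L) # until something clears it
})

test_that("a door contact alone never sets the in-room state", {
  iv <- mk_iv("n001", "b005", 100, 120L)  # door of room 2 only
  h <- annotate_inroom(impute_history(iv, shift_spec(2), quiet = TRUE),
                       placement3, quiet = TRUE)
  expect_equal(nrow(h$state), 0L)
  expect_null(state_room(h, "n001", T0 + 150))
})

test_that("contact with an anchor outside the room clears the state", {
  sh <- shift_spec(2)
  # enter room 2 (vitals), then touch a corridor (common) anchor
  iv <- mk_iv(c("n001", "n001"), c("b008", "b013"), c(100, 400), c(60L, 10L))
  h <- annotate_inroom(impute_history(iv, sh, quiet = TRUE), placement3,
                       quiet = TRUE)
  expect_equal(state_room(h, "n001", T0 + 399), 2L)
  expect_null(state_room(h, "n001", T0 + 400))
  # another room's door also clears (it lies outside room 2)
  iv2 <- mk_iv(c("n001", "n001"), c("b008", "b001"), c(100, 400), c(60L, 10L))
  h2 <- annotate_inroom(impute_history(iv2, sh, quiet = TRUE), placement3,
                        quiet = TRUE)
  expect_null(state_room(h2, "n001", T0 + 400))
  # but room 2's own door does not clear
  iv3 <- mk_iv(c("n001", "n001"), c("b008", "b005"), c(100, 400), c(60L, 10L))
  h3 <- annotate_inroom(impute_history(iv3, sh, quiet = TRUE), placement3,
                        quiet = TRUE)
  expect_equal(state_room(h3, "n001", T0 + 405), 2L)
})

test_that("a contact with an unknown anchor is an error naming it", {
  iv <- mk_iv("n001", "b099", 0, 30L)
  expect_error(annotate_inroom(impute_history(iv, shift_spec(2), quiet = TRUE),
                               placement3),
               "b099")
})

test_that("simultaneous interior contacts resolve to the most recent room", {
  sh <- shift_spec(2)
  # room 1 vitals from t=100 (long), room 2 vitals begins later at t=200
  iv <- mk_iv(c("n001", "n001"), c("b004", "b008"), c(100, 200), c(300L, 60L))
  h <- annotate_inroom(impute_history(iv, sh, quiet = TRUE), placement3,
                       quiet = TRUE)
  expect_equal(state_room(h, "n001", T0 + 150), 1L)
  expect_equal(state_room(h, "n001", T0 + 220), 2L)
})

test_that("contact graphs count contact seconds and match a per-second count", {
  sh <- shift_spec(2)
  iv <- mk_iv(c("n001", "n001"), c("pr002", "b004"), c(0, 5), c(1L, 30L))
  h <- impute_history(iv, sh, quiet = TRUE)
  g <- contact_graph(h, T0, T0 + 60)
  expect_equal(g$weight[g$from == "n001" & g$to == "pr002"], 1)
  expect_equal(attr(g, "roles")$role[attr(g, "roles")$badge == "b004"], "anchor")
  # empty window
  expect_equal(nrow(contact_graph(h, T0 + 50, T0 + 60)), 0L)
  # oracle: per-second triple count within the window
  set.seed(31)
  ivr <- random_interval_set(n_badges = 6, n_iv = 25, span = 500)
  hr <- impute_history(ivr, sh, quiet = TRUE)
  tri <- history_triples(hr)
  win <- tri[tri$t >= as.numeric(T0) + 100 & tri$t < as.numeric(T0) + 400, ]
  key <- paste(pmin(win$badge, win$contact), pmax(win$badge, win$contact))
  g2 <- contact_graph(hr, T0 + 100, T0 + 400)
  got <- setNames(g2$weight, paste(g2$from, g2$to))
  # each unordered HCP-HCP pair appears twice in the triples, anchors once
  expected <- tapply(rep(1, nrow(win)), key, sum)
  both_hcp <- !grepl("^b[0-9]", sub(" .*", "", names(expected)))
  expected[both_hcp] <- expected[both_hcp] / 2
  expect_equal(sort(got), sort(expected[names(got)]), ignore_attr = TRUE)
  # weight additivity over disjoint windows
  g_a <- contact_graph(hr, T0 + 100, T0 + 250)
  g_b <- contact_graph(hr, T0 + 250, T0 + 400)
  tot <- tapply(c(g_a$weight, g_b$weight),
                c(paste(g_a$from, g_a$to), paste(g_b$from, g_b$to)), sum)
  expect_equal(sort(got), sort(tot[names(got)]), ignore_attr = TRUE)
  # windows outside the span are rejected
  expect_error(contact_graph(h, h$t0 - 10, T0), "within the history span")
})
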