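# Shared fixtures and independent brute-force oracles.
# The oracles deliberately use the most literal formulation of each rule
# (pairwise rewriting to a fixpoint, per-second expansion) so they stay
# independent of the vectorised implementation paths they check.

T0 <- as.POSIXct("2023-04-21 08:00:00", tz = "UTC")

mk_raw <- function(rep, det, t, d, dur) {
  raw_records(rep, det, T0 + t, d, dur)
}

mk_iv <- function(rep, det, t, dur, d = 40L) {
  contact_intervals(rep, det, T0 + t, d, dur)
}

# ---- literal pairwise merge oracle ------------------------------------
# Mirrors every interval, then repeatedly rewrites any (a,b)/(b,a) pair of
# overlapping spans (with slack) to [min start, max end] and the minimum
# distance, until nothing changes.
oracle_merge <- function(iv, slack = 0) {
  sp <- data.frame(rep = iv$reporter, det = iv$detected,
                   s = as.numeric(iv$start_time),
                   e = as.numeric(iv$start_time) + iv$duration_s,
                   d = as.numeric(iv$distance_in))
  sp <- unique(rbind(sp, data.frame(rep = sp$det, det = sp$rep,
                                    s = sp$s, e = sp$e, d = sp$d)))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(sp))) {
      for (j in seq_len(nrow(sp))) {
        if (i == j) next
        if (sp$rep[i] == sp$det[j] && sp$det[i] == sp$rep[j] &&
            sp$s[i] < sp$e[j] + slack && sp$s[j] < sp$e[i] + slack) {
          ns <- min(sp$s[i], sp$s[j]); ne <- max(sp$e[i], sp$e[j])
          nd <- min(sp$d[i], sp$d[j])
          if (sp$s[i] != ns || sp$e[i] != ne || sp$d[i] != nd ||
              sp$s[j] != ns || sp$e[j] != ne || sp$d[j] != nd) {
            sp$s[c(i, j)] <- ns; sp$e[c(i, j)] <- ne; sp$d[c(i, j)] <- nd
            changed <- TRUE
          }
        }
      }
    }
    sp <- unique(sp)
    if (!changed) break
  }
  sp <- sp[order(sp$rep, sp$det, sp$s), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

normalize_intervals <- function(iv) {
  sp <- unique(data.frame(rep = iv$reporter, det = iv$detected,
                          s = as.numeric(iv$start_time),
                          e = as.numeric(iv$start_time) + iv$duration_s,
                          d = as.numeric(iv$distance_in)))
  sp <- sp[order(sp$rep, sp$det, sp$s), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

# ---- per-second imputation oracle -------------------------------------
# Expands every interval into its (second, badge, contact) triples, forces
# symmetry, drops anchor primary keys and anchor-anchor intervals.
oracle_impute_triples <- function(iv, shift) {
  t0 <- as.numeric(shift$start); t1 <- as.numeric(shift$end)
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    a <- iv$reporter[i]; b <- iv$detected[i]
    if (is_anchor(a) && is_anchor(b)) next
    s <- max(as.numeric(iv$start_time[i]), t0)
    e <- min(as.numeric(iv$start_time[i]) + iv$duration_s[i], t1)
    if (e <= s) next
    secs <- seq.int(s, e - 1)
    rows[[length(rows) + 1L]] <-
      data.frame(t = c(secs, secs), badge = c(rep(a, length(secs)), rep(b, length(secs))),
                 contact = c(rep(b, length(secs)), rep(a, length(secs))))
  }
  if (length(rows) == 0) {
    return(data.frame(t = numeric(), badge = character(), contact = character()))
  }
  tri <- unique(do.call(rbind, rows))
  tri <- tri[!is_anchor(tri$badge), , drop = FALSE]
  tri <- tri[order(tri$t, tri$badge, tri$contact), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}

history_triples <- function(history) {
  cr <- history$contacts
  if (nrow(cr) == 0) {
    return(data.frame(t = numeric(), badge = character(), contact = character()))
  }
  rows <- lapply(seq_len(nrow(cr)), function(i) {
    secs <- seq.int(as.numeric(cr$start[i]), as.numeric(cr$end[i]) - 1)
    data.frame(t = secs, badge = cr$badge[i], contact = cr$contact[i])
  })
  tri <- unique(do.call(rbind, rows))
  tri <- tri[order(tri$t, tri$badge, tri$contact), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}

# ---- random instance generators ---------------------------------------
random_interval_set <- function(n_badges = 6, n_iv = 20, span = 600,
                                anchor_frac = 0.3, allow_stub = TRUE) {
  n_anchor <- max(0L, round(n_badges * anchor_frac))
  badges <- c(badge_label("anchor", seq_len(n_anchor) + 30L),
              badge_label(sample(c("nurse", "provider", "support"),
                                 n_badges - n_anchor, replace = TRUE),
                          sample.int(40, n_badges - n_anchor)))
  rep <- badges[sample.int(length(badges), n_iv, replace = TRUE)]
  det <- vapply(rep, function(r) {
    others <- setdiff(badges, r)
    others[sample.int(length(others), 1L)]
  }, character(1))
  dur <- ifelse(runif(n_iv) < (if (allow_stub) 0.2 else 0),
                10L, 15L * sample.int(20, n_iv, replace = TRUE))
  mk_iv(rep, unname(det), sample.int(span, n_iv, replace = TRUE), dur,
        d = sample(12:80, n_iv, replace = TRUE))
}

# ---- recovery comparison helpers --------------------------------------
# True episodes separated by a gap the firmware cannot see (less than a
# full high-level cycle between under-threshold samples) are coalesced
# before comparing against reconstructed intervals.
coalesce_truth <- function(truth, gap_max_s) {
  truth$a <- pmin(truth$badge_a, truth$badge_b)
  truth$b <- pmax(truth$badge_a, truth$badge_b)
  out <- lapply(split(truth, paste(truth$a, truth$b)), function(d) {
    d <- d[order(d$true_start), ]
    s <- as.numeric(d$true_start); e <- as.numeric(d$true_end)
    gid <- cumsum(c(TRUE, s[-1] - cummax(e)[-length(e)] > gap_max_s))
    data.frame(a = d$a[1], b = d$b[1],
               s = as.numeric(tapply(s, gid, min)),
               e = as.numeric(tapply(e, gid, max)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

unordered_spans <- function(iv) {
  unique(data.frame(a = pmin(iv$reporter, iv$detected),
                    b = pmax(iv$reporter, iv$detected),
                    s = as.numeric(iv$start_time),
                    e = as.numeric(iv$start_time) + iv$duration_s))
}

# worst boundary error of the best-overlapping reconstructed span
boundary_errors <- function(episodes, spans) {
  vapply(seq_len(nrow(episodes)), function(i) {
    cand <- spans[spans$a == episodes$a[i] & spans$b == episodes$b[i] &
                    spans$e > episodes$s[i] & spans$s < episodes$e[i], , drop = FALSE]
    if (nrow(cand) == 0) return(Inf)
    ov <- pmin(cand$e, episodes$e[i]) - pmax(cand$s, episodes$s[i])
    jb <- which.max(ov)
    max(abs(cand$s[jb] - episodes$s[i]), abs(cand$e[jb] - episodes$e[i]))
  }, numeric(1))
}

# noiseless small-unit scenario used by the recovery tests
noiseless_scenario <- function(seed = 5) {
  sim_scenario(seed = seed, rooms = 6,
               day_roster = c(provider = 2L, nurse = 4L, support = 2L),
               distance_noise_in = 0, clock_drift_s = 0,
               receptacle_artifacts = FALSE)
}

# first `hours` of a simulated shift as tracks + truth + raw records
noiseless_hour <- function(seed = 5, hours = 1) {
  sc <- noiseless_scenario(seed)
  lay <- generate_layout(sc)
  sh <- shift_spec(2, sc$first_day)
  tr <- simulate_movement(sc, lay, sh)
  n <- as.integer(hours * 3600 / sc$low_cycle_s)
  tr1 <- badge_tracks(tr$times[seq_len(n)], tr$badges,
                      tr$x[seq_len(n), ], tr$y[seq_len(n), ])
  sm <- micutrace:::pair_samples(tr1, lay$placement,
                                 max_in = sc$contact_threshold_in + 1,
                                 min_hcp_in = sc$mobility$body_min_in)
  truth <- true_contacts(tr1, lay$placement, sc$contact_threshold_in,
                         samples = sm)
  offs <- setNames(rep(0, length(tr1$badges) + nrow(lay$placement)),
                   c(tr1$badges, lay$placement$anchor))
  records <- sense_and_emit(tr1, sc, lay$placement, samples = sm,
                            clock_offsets = offs)
  list(scenario = sc, layout = lay, shift = sh, tracks = tr1,
       truth = truth, records = records)
}

state_room <- function(history, badge, t) {
  st <- micutrace:::state_at(history, badge, as.numeric(t))
  if (is.null(st)) NULL else st$room
}
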