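# Agent-based MICU badge simulator.
#
# Healthcare-worker agents alternate dwell episodes at stations (patient
# rooms, nurse-station desks) with walks along the corridor, under a
# semi-Markov mobility model with role-specific destination and dwell
# distributions. Their continuous trajectories are sampled on the badge
# low-level signalling grid; a UWB sensing model with Gaussian distance
# noise, per-badge clock offsets and the 15-second high-level processing
# cycle turns true proximity into raw start/end records in the exact file
# format of the processing pipeline, alongside ground-truth contact
# episodes for recovery testing.

#' Simulation scenario
#'
#' Bundles the deployment constants and simulator knobs. Defaults mirror
#' the emulated MICU deployment: 26 single-occupancy patient rooms with 4
#' anchors each, a six-foot (72 inch) contact threshold, UWB distance
#' noise of about ten centimetres, a low-level signalling cycle of a few
#' seconds, the 15-second high-level contact-processing cycle, day-shift
#' roster 12 providers / 19 nurses / 12 support staff and night-shift
#' roster 6 / 15 / 8, and fourteen working 12-hour shifts indexed 1-14.
#'
#' @param seed base random seed for the scenario.
#' @param rooms number of patient rooms.
#' @param day_roster,night_roster named counts (`provider`, `nurse`,
#'   `support`) of badge-wearing staff per shift kind.
#' @param shifts integer shift indices simulated by [run_pipeline()].
#' @param first_day calendar date of shift 0's morning.
#' @param contact_threshold_in contact distance threshold in inches.
#' @param distance_noise_in SD of the Gaussian distance-measurement noise
#'   in inches (4 in is roughly the ten-centimetre UWB accuracy);
#'   truncated so sensed distances stay non-negative.
#' @param low_cycle_s low-level signalling period in seconds.
#' @param high_cycle_s high-level contact-processing period in seconds;
#'   must be a multiple of `low_cycle_s`.
#' @param clock_drift_s badge clocks drift between synchronising scans;
#'   each badge gets a constant offset drawn uniformly from
#'   `[-clock_drift_s, clock_drift_s]` seconds, applied to reported times
#'   only.
#' @param receptacle_artifacts emit the sub-12-inch records produced by
#'   badges lying together in a receptacle around handout and turn-in.
#' @param extra_badges powered-on unworn badges per shift; they power off
#'   within half an hour of shift start.
#' @param common_anchors number of corridor (common-area) anchors; the
#'   emulated deployment had none.
#' @param pixels_per_foot layout-image scale for the placement file.
#' @param mobility optional list overriding the role-specific mobility
#'   parameters (see the vignette).
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 1L,
                         rooms = 26L,
                         day_roster = c(provider = 12L, nurse = 19L, support = 12L),
                         night_roster = c(provider = 6L, nurse = 15L, support = 8L),
                         shifts = 1:14,
                         first_day = "2023-04-20",
                         contact_threshold_in = 72,
                         distance_noise_in = 4,
                         low_cycle_s = 3L,
                         high_cycle_s = 15L,
                         clock_drift_s = 5L,
                         receptacle_artifacts = TRUE,
                         extra_badges = 2L,
                         common_anchors = 0L,
                         pixels_per_foot = 10,
                         mobility = list()) {
  stopifnot(rooms >= 1, high_cycle_s %% low_cycle_s == 0,
            contact_threshold_in > 0, distance_noise_in >= 0,
            clock_drift_s >= 0, all(day_roster >= 0), all(night_roster >= 0))
  mob <- utils::modifyList(default_mobility(), mobility)
  structure(list(
    seed = as.integer(seed), rooms = as.integer(rooms),
    day_roster = day_roster, night_roster = night_roster,
    shifts = as.integer(shifts), first_day = first_day,
    contact_threshold_in = contact_threshold_in,
    distance_noise_in = distance_noise_in,
    low_cycle_s = as.integer(low_cycle_s),
    high_cycle_s = as.integer(high_cycle_s),
    clock_drift_s = as.integer(clock_drift_s),
    receptacle_artifacts = isTRUE(receptacle_artifacts),
    extra_badges = as.integer(extra_badges),
    common_anchors = as.integer(common_anchors),
    pixels_per_foot = pixels_per_foot,
    mobility = mob
  ), class = "sim_scenario")
}

default_mobility <- function() {
  list(
    speed_ft_s = 4,                 # walking speed along the corridor
    standoff_ft = c(1.5, 3.5),      # dwell distance from the station point:
                                    # a person works at arm's length from the
                                    # sink/monitor, never on top of it
    body_min_in = 15,               # hard-core floor on badge-to-badge
                                    # distance (badges are worn on the chest;
                                    # bodies exclude closer approach)
    start_stagger_s = 600,          # arrival spread after shift start
    nurse = list(assigned_rooms = 2, p_room = 0.70, p_station = 0.25,
                 dwell_room_s = 540, dwell_station_s = 300),
    provider = list(p_room = 0.75, p_station = 0.25,
                    dwell_room_s = 240, dwell_station_s = 240),
    support = list(p_room = 0.50, p_station = 0.50,
                   dwell_room_s = 180, dwell_station_s = 360)
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("<sim_scenario: %d rooms, day %d/%d/%d night %d/%d/%d ",
                     "(provider/nurse/support), threshold %g in, seed %d>\n"),
              x$rooms, x$day_roster["provider"], x$day_roster["nurse"],
              x$day_roster["support"], x$night_roster["provider"],
              x$night_roster["nurse"], x$night_roster["support"],
              x$contact_threshold_in, x$seed))
  invisible(x)
}

#' Badge position tracks on the sensing grid
#'
#' Positions of badge-wearing agents sampled on the low-level signalling
#' grid, in feet. Used as the interface between the mobility model and
#' the sensing model, and constructible directly for scripted tests.
#'
#' @param times numeric vector of sample times (absolute seconds, evenly
#'   spaced by the low cycle).
#' @param badges character vector of badge labels (columns).
#' @param x,y numeric matrices `length(times)` x `length(badges)` of
#'   positions in feet.
#' @return object of class `badge_tracks`.
#' @export
badge_tracks <- function(times, badges, x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == length(times), ncol(x) == length(badges),
            all(dim(x) == dim(y)))
  structure(list(times = as.numeric(times), badges = as.character(badges),
                 x = x, y = y),
            class = "badge_tracks")
}

#' Simulate agent movement for one shift
#'
#' Each agent starts at the unit entry shortly after shift start and then
#' alternates station dwells with corridor walks: nurses favour their
#' assigned rooms, providers round across all rooms in a personal order,
#' support staff split time between the nurse stations and sporadic room
#' visits. Routes go through the room door to the corridor walk line, so
#' door-anchor pass-bys and corridor encounters arise naturally.
#' Deterministic given the scenario seed and shift index.
#'
#' @param scenario a [sim_scenario()].
#' @param layout a [generate_layout()] result.
#' @param shift a [shift_spec()].
#' @return a `badge_tracks` object with a `roles` attribute.
#' @export
simulate_movement <- function(scenario, layout, shift) {
  roster <- if (shift$kind == "day") scenario$day_roster else scenario$night_roster
  mob <- scenario$mobility
  with_local_seed(derive_seed(scenario$seed, shift$index), {
    badges <- roster_badges(roster)
    roles <- role_of(badges)
    t0 <- as.numeric(shift$start); t1 <- as.numeric(shift$end)
    ticks <- seq(t0, t1 - scenario$low_cycle_s, by = scenario$low_cycle_s)
    nt <- length(ticks); na <- length(badges)
    X <- matrix(NA_real_, nt, na); Y <- matrix(NA_real_, nt, na)
    rooms_all <- unique(layout$stations$room[is_patient_room(layout$stations$room)])
    for (i in seq_len(na)) {
      wp <- agent_waypoints(roles[i], t0, t1, layout, rooms_all, mob)
      X[, i] <- stats::approx(wp$t, wp$x, xout = ticks, rule = 2)$y
      Y[, i] <- stats::approx(wp$t, wp$y, xout = ticks, rule = 2)$y
    }
    tr <- badge_tracks(ticks, badges, X, Y)
    attr(tr, "roles") <- roles
    tr
  })
}

# draw shift badge labels from overprovisioned per-role pools
roster_badges <- function(roster) {
  lab <- function(role, n) {
    pool <- 2L * n + 4L
    badge_label(role, sort(sample.int(pool, n)))
  }
  c(lab("provider", roster[["provider"]]),
    lab("nurse", roster[["nurse"]]),
    lab("support", roster[["support"]]))
}

# one agent's (t, x, y) waypoint sequence: entry -> dwell/walk episodes
agent_waypoints <- function(role, t0, t1, layout, rooms_all, mob) {
  pm <- mob[[role]]
  speed <- mob$speed_ft_s
  # dwell point at arm's length from the station, on its approach side,
  # so walk legs never pass over the anchor itself
  standoff_at <- function(target, from) {
    ang <- atan2(from[2] - target[2], from[1] - target[1]) +
      runif(1, -pi / 3, pi / 3)
    r <- runif(1, mob$standoff_ft[1], mob$standoff_ft[2])
    c(target[1] + r * cos(ang), target[2] + r * sin(ang))
  }
  entry <- layout$entry
  ns <- layout$nurse_stations
  assigned <- if (role == "nurse") {
    rooms_all[sample.int(length(rooms_all), min(pm$assigned_rooms, length(rooms_all)))]
  } else if (role == "provider") {
    rooms_all[sample.int(length(rooms_all))]   # personal rounding order
  } else rooms_all
  pick1 <- function(v) v[sample.int(length(v), 1L)]
  round_pos <- 0L
  t <- t0 + runif(1, 0, mob$start_stagger_s)
  wt <- c(t0, t); wx <- c(entry["x"], entry["x"]); wy <- c(entry["y"], entry["y"])
  cur <- c(entry["x"], entry["y"]); cur_room <- NA_character_
  while (t < t1) {
    u <- runif(1)
    if (u < pm$p_room) {
      dest_room <- if (role == "nurse") {
        pick1(assigned)
      } else if (role == "provider") {
        round_pos <- round_pos %% length(assigned) + 1L
        assigned[round_pos]
      } else pick1(rooms_all)
      dwell_mean <- pm$dwell_room_s
    } else if (u < pm$p_room + pm$p_station) {
      dest_room <- NA_character_
      dwell_mean <- pm$dwell_station_s
    } else {
      dest_room <- pick1(rooms_all)
      dwell_mean <- pm$dwell_room_s / 2
    }
    # destination point
    if (!is.na(dest_room)) {
      st <- layout$stations[layout$stations$room == dest_room &
                              layout$stations$station %in% .INTERIOR_STATIONS, ]
      stw <- c(vitals = 0.5, sink = 0.25, computer = 0.25)
      pick <- st[sample.int(nrow(st), 1L, prob = stw[st$station]), ]
      door <- layout$stations[layout$stations$room == dest_room &
                                layout$stations$station == "door", ]
      dest <- standoff_at(c(pick$x, pick$y), c(door$x, door$y))
      via_in <- rbind(c(door$x, layout$walk_y), c(door$x, door$y))
    } else {
      k <- sample.int(nrow(ns), 1L)
      dest <- standoff_at(c(ns$x[k], ns$y[k]), c(ns$x[k], ns$y[k] - 5))
      via_in <- NULL
    }
    # route: leave current room via its door, walk the corridor, enter
    pts <- cur
    if (!is.na(cur_room)) {
      door0 <- layout$stations[layout$stations$room == cur_room &
                                 layout$stations$station == "door", ]
      pts <- rbind(pts, c(door0$x, door0$y), c(door0$x, layout$walk_y))
    } else {
      pts <- rbind(pts, c(cur[1], layout$walk_y))
    }
    if (!is.null(via_in)) pts <- rbind(pts, c(via_in[1, 1], layout$walk_y), via_in)
    else pts <- rbind(pts, c(dest[1], layout$walk_y))
    pts <- rbind(pts, dest)
    seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    keep <- seg > 1e-9
    for (j in which(keep)) {
      t <- t + seg[j] / speed
      wt <- c(wt, t); wx <- c(wx, pts[j + 1, 1]); wy <- c(wy, pts[j + 1, 2])
    }
    dwell <- rgamma(1, shape = 2, scale = dwell_mean / 2)
    t <- t + dwell
    wt <- c(wt, t); wx <- c(wx, dest[1]); wy <- c(wy, dest[2])
    cur <- dest; cur_room <- dest_room
  }
  list(t = wt, x = wx, y = wy)
}

# ---- proximity sampling ------------------------------------------------

# all (tick, badge, badge) pairs within max_in inches, via spatial hashing
# on a grid of max_in-sized cells; includes HCP-HCP and HCP-anchor pairs.
pair_samples <- function(tracks, placement = NULL, max_in = 88, min_hcp_in = 0) {
  cell_ft <- max_in / 12
  nt <- length(tracks$times); na <- length(tracks$badges)
  P <- data.table(ti = rep.int(seq_len(nt), na),
                  a = rep(seq_len(na), each = nt),
                  x = as.vector(tracks$x), y = as.vector(tracks$y))
  P[, `:=`(cx = floor(x / cell_ft), cy = floor(y / cell_ft))]
  setkey(P, ti, cx, cy)
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  hh <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    Q <- P[, .(ti, cx = cx + offs$dx[k], cy = cy + offs$dy[k], a2 = a,
               x2 = x, y2 = y)]
    m <- P[Q, on = .(ti, cx, cy), nomatch = NULL, allow.cartesian = TRUE,
           .(ti, a, b = a2, x, y, x2, y2)]
    hh[[k]] <- m[a < b]
  }
  hp <- rbindlist(hh)
  hp[, d_in := pmax(12 * sqrt((x - x2)^2 + (y - y2)^2), min_hcp_in)]
  hp <- hp[d_in <= max_in, .(ti, a, b, d_in)]
  out <- data.table(ti = hp$ti,
                    u = tracks$badges[hp$a], v = tracks$badges[hp$b],
                    d_in = hp$d_in)
  if (!is.null(placement) && nrow(placement) > 0) {
    A <- data.table(anchor = placement$anchor,
                    ax = placement$x / (attr(placement, "pixels_per_foot") %||% 10),
                    ay = placement$y / (attr(placement, "pixels_per_foot") %||% 10))
    A[, `:=`(cx = floor(ax / cell_ft), cy = floor(ay / cell_ft))]
    ha <- vector("list", nrow(offs))
    for (k in seq_len(nrow(offs))) {
      Q <- A[, .(cx = cx + offs$dx[k], cy = cy + offs$dy[k], anchor, ax, ay)]
      m <- P[Q, on = .(cx, cy), nomatch = NULL, allow.cartesian = TRUE,
             .(ti, a, anchor, x, y, ax, ay)]
      ha[[k]] <- m
    }
    hpa <- rbindlist(ha)
    if (nrow(hpa)) {
      hpa[, d_in := 12 * sqrt((x - ax)^2 + (y - ay)^2)]
      hpa <- hpa[d_in <= max_in]
      out <- rbind(out, data.table(ti = hpa$ti, u = tracks$badges[hpa$a],
                                   v = hpa$anchor, d_in = hpa$d_in))
    }
  }
  setorder(out, u, v, ti)
  out
}

#' Ground-truth contact episodes from position tracks
#'
#' A true contact is a maximal period during which the true distance
#' between two badges (HCP-HCP or HCP-anchor) stays at or below the
#' contact threshold, evaluated on the low-cycle sampling grid; an
#' episode covering grid times `[t_i, t_j]` spans `[t_i, t_j + step)`.
#'
#' @param tracks a `badge_tracks` object.
#' @param placement optional [anchor_placement()] adding HCP-anchor
#'   contacts.
#' @param threshold_in contact distance threshold in inches.
#' @param samples optional precomputed [pair_samples()] table.
#' @return data frame with `badge_a`, `badge_b`, `true_start`,
#'   `true_end` (`POSIXct`), `min_distance_in`, `duration_s`.
#' @export
true_contacts <- function(tracks, placement = NULL, threshold_in = 72,
                          samples = NULL) {
  step <- if (length(tracks$times) > 1) diff(tracks$times[1:2]) else 1
  sm <- samples %||% pair_samples(tracks, placement, max_in = threshold_in)
  sm <- sm[d_in <= threshold_in]
  empty <- data.frame(badge_a = character(), badge_b = character(),
                      true_start = .POSIXct(numeric(), tz = .TZ),
                      true_end = .POSIXct(numeric(), tz = .TZ),
                      min_distance_in = numeric(), duration_s = numeric())
  if (nrow(sm) == 0) return(empty)
  setorder(sm, u, v, ti)
  sm[, gid := cumsum(c(TRUE, diff(ti) != 1L)), by = .(u, v)]
  ep <- sm[, .(t0 = min(ti), t1 = max(ti), dmin = min(d_in)), by = .(u, v, gid)]
  out <- data.frame(badge_a = ep$u, badge_b = ep$v,
                    true_start = .POSIXct(tracks$times[ep$t0], tz = .TZ),
                    true_end = .POSIXct(tracks$times[ep$t1] + step, tz = .TZ),
                    min_distance_in = ep$dmin,
                    duration_s = tracks$times[ep$t1] + step - tracks$times[ep$t0])
  out <- out[order(out$badge_a, out$badge_b, out$true_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sense trajectories and emit raw badge records
#'
#' Models the badge firmware: every low cycle each badge measures the
#' distance to its neighbours with Gaussian noise; the high-level cycle
#' (15 s) opens a contact on the first under-threshold sample, keeps it
#' alive while samples keep arriving, and purges it after a full high
#' cycle without one. A purged contact whose under-threshold samples
#' spanned less than about half a high cycle is dropped without an end
#' record -- the firmware effectively ignores contacts shorter than the
#' processing cycle, leaving a lone start record. Otherwise an end record
#' is written with the same start time and a duration rounded to a
#' multiple of the high cycle. Each badge senses independently in both
#' directions of a pair and reports times shifted by its own constant
#' clock offset.
#'
#' @param tracks a `badge_tracks` object.
#' @param scenario a [sim_scenario()].
#' @param placement optional [anchor_placement()]; anchors sense and
#'   report too.
#' @param samples optional precomputed [pair_samples()] table.
#' @param clock_offsets optional named vector of per-badge clock offsets
#'   in seconds (default: drawn uniformly from the scenario's drift
#'   range).
#' @return a `raw_records` data frame, sorted by reporter then time (the
#'   published raw files are not time-ordered either).
#' @export
sense_and_emit <- function(tracks, scenario, placement = NULL, samples = NULL,
                           clock_offsets = NULL) {
  thr <- scenario$contact_threshold_in
  noise <- scenario$distance_noise_in
  high <- scenario$high_cycle_s
  sm <- samples %||% pair_samples(tracks, placement,
                                  max_in = thr + 4 * max(noise, 0) + 1)
  all_badges <- c(tracks$badges, if (!is.null(placement)) placement$anchor)
  if (is.null(clock_offsets)) {
    drift <- scenario$clock_drift_s
    clock_offsets <- setNames(
      if (drift > 0) sample(seq(-drift, drift), length(all_badges), replace = TRUE)
      else rep(0L, length(all_badges)),
      all_badges)
  }
  if (nrow(sm) == 0) return(new_records(class2 = "raw_records"))
  # each badge of a pair senses independently
  dir <- rbind(sm[, .(rep_ = u, det = v, ti, d_in)],
               sm[, .(rep_ = v, det = u, ti, d_in)])
  setorder(dir, rep_, det, ti)
  dir[, sensed := pmax(0, d_in + (if (noise > 0) rnorm(.N, 0, noise) else 0))]
  under <- dir[sensed <= thr]
  if (nrow(under) == 0) return(new_records(class2 = "raw_records"))
  tms <- tracks$times
  under[, tt := tms[ti]]
  under[, gid := cumsum(c(TRUE, diff(tt) > high)), by = .(rep_, det)]
  # the reported distance is the episode's median sensed distance ("around
  # the time of the contact interval"), robust to one close pass-by sample
  eps <- under[, .(first_t = min(tt), last_t = max(tt),
                   first_d = stats::median(sensed)),
               by = .(rep_, det, gid)]
  eps[, k := as.integer(round((last_t - first_t) / high))]
  off <- clock_offsets[eps$rep_]
  start_t <- eps$first_t + off
  d_rep <- as.integer(round(eps$first_d))
  starts <- data.frame(reporter = eps$rep_, detected = eps$det,
                       start_time = start_t, distance_in = d_rep,
                       duration_s = 0L)
  ends <- data.frame(reporter = eps$rep_, detected = eps$det,
                     start_time = start_t, distance_in = d_rep,
                     duration_s = eps$k * high)[eps$k >= 1L, , drop = FALSE]
  rec <- rbind(starts, ends)
  rec <- rec[order(rec$reporter, rec$start_time, rec$detected, rec$duration_s), ,
             drop = FALSE]
  out <- new_records(rec$reporter, rec$detected,
                     .POSIXct(rec$start_time, tz = .TZ),
                     rec$distance_in, rec$duration_s, class2 = "raw_records")
  rownames(out) <- NULL
  out
}

# sub-12-inch receptacle records at handout/turn-in plus the extra
# powered-on unworn badges that are switched off within half an hour
receptacle_records <- function(scenario, shift, worn_badges) {
  t0 <- as.numeric(shift$start); t1 <- as.numeric(shift$end)
  high <- scenario$high_cycle_s
  rec <- list()
  emit_pair <- function(a, b, t, dur_s, dist_in) {
    k <- max(1L, as.integer(round(dur_s / high)))
    rbind(data.frame(reporter = c(a, b), detected = c(b, a), start_time = t,
                     distance_in = as.integer(dist_in), duration_s = 0L),
          data.frame(reporter = c(a, b), detected = c(b, a), start_time = t,
                     distance_in = as.integer(dist_in), duration_s = k * high))
  }
  if (scenario$extra_badges >= 2L) {
    # unworn badges sit together in the receptacle, then power off
    roles <- c("nurse", "support", "provider")
    extras <- vapply(seq_len(scenario$extra_badges), function(i)
      badge_label(roles[(i - 1L) %% 3L + 1L], 90L + i), character(1))
    off_t <- t0 + runif(length(extras), 300, 1800)  # within half an hour
    for (i in seq_len(length(extras) - 1L)) {
      a <- extras[i]; b <- extras[i + 1L]
      dur <- min(off_t[i], off_t[i + 1L]) - t0
      rec[[length(rec) + 1L]] <-
        emit_pair(a, b, t0, dur, round(runif(1, 2, 11)))
    }
  }
  if (length(worn_badges) >= 2L) {
    # turned-in badges awaiting their scan at shift end
    n_pairs <- min(3L, length(worn_badges) %/% 2L)
    pick <- sample(worn_badges, 2L * n_pairs)
    for (i in seq_len(n_pairs)) {
      rec[[length(rec) + 1L]] <-
        emit_pair(pick[2 * i - 1], pick[2 * i], t1 - round(runif(1, 60, 480)),
                  runif(1, 60, 300), round(runif(1, 2, 11)))
    }
  }
  if (length(rec) == 0) return(new_records(class2 = "raw_records"))
  df <- do.call(rbind, rec)
  new_records(df$reporter, df$detected, .POSIXct(df$start_time, tz = .TZ),
              df$distance_in, df$duration_s, class2 = "raw_records")
}

#' Simulate one complete shift
#'
#' Runs layout generation, agent movement, ground-truth extraction and
#' the sensing model for one shift; deterministic given the scenario seed
#' and shift index.
#'
#' @param scenario a [sim_scenario()].
#' @param shift_index shift index (its parity selects the roster).
#' @param layout optional precomputed [generate_layout()].
#' @return a list with `records` (raw records, shuffled like a real
#'   extract), `truth` (ground-truth contacts), `placement`, `tracks`,
#'   and `shift`.
#' @export
simulate_shift <- function(scenario, shift_index = 1L, layout = NULL) {
  layout <- layout %||% generate_layout(scenario)
  shift <- shift_spec(shift_index, first_day = scenario$first_day)
  tracks <- simulate_movement(scenario, layout, shift)
  with_local_seed(derive_seed(scenario$seed, 100000L + shift_index), {
    sm <- pair_samples(tracks, layout$placement,
                       max_in = scenario$contact_threshold_in +
                         4 * max(scenario$distance_noise_in, 0) + 1,
                       min_hcp_in = scenario$mobility$body_min_in)
    truth <- true_contacts(tracks, layout$placement,
                           threshold_in = scenario$contact_threshold_in,
                           samples = sm)
    records <- sense_and_emit(tracks, scenario, layout$placement, samples = sm)
    if (scenario$receptacle_artifacts) {
      records <- rbind(records,
                       receptacle_records(scenario, shift, tracks$badges))
      class(records) <- c("raw_records", "data.frame")
    }
    records <- records[order(records$reporter, records$start_time,
                             records$detected, records$duration_s), , drop = FALSE]
    rownames(records) <- NULL
    list(records = records, truth = truth, placement = layout$placement,
         tracks = tracks, shift = shift)
  })
}
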