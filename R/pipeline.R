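# End-to-end pipeline: simulate -> make intervals -> impute histories ->
# summarise, with a run manifest. Shift files are numbered with 2-digit
# indices (intervals01.json.xz, histories01.json.xz, ...), mirroring the
# published naming.

#' Run the full simulate/process/summarise pipeline
#'
#' Executes the configured stages in order, writing per-shift raw,
#' interval and history files, summary CSVs, the anchor placement file
#' and a JSON manifest with the package version, seed, parameters and
#' md5 hashes of every artifact. Reruns with the same configuration
#' produce byte-identical interval and history files.
#'
#' Configuration is a YAML file (or an equivalent named list) with keys:
#' `out_dir`; `scenario` (arguments of [sim_scenario()], including
#' `seed` and `shifts`); optional `min_distance_in` (12),
#' `merge_slack_s` (0), `annotate` (TRUE), and `stages` (subset of
#' `simulate`, `intervals`, `histories`, `summarize`).
#'
#' @param config path to a YAML configuration file, or a named list.
#' @param out_dir overrides the configured output directory.
#' @param quiet suppress stage logs.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("config is missing required key 'out_dir'", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages %||% c("simulate", "intervals", "histories", "summarize")
  sc_args <- cfg$scenario %||% list()
  if (!is.null(sc_args$day_roster)) sc_args$day_roster <- unlist(sc_args$day_roster)
  if (!is.null(sc_args$night_roster)) sc_args$night_roster <- unlist(sc_args$night_roster)
  scenario <- do.call(sim_scenario, sc_args)
  min_in <- cfg$min_distance_in %||% 12L
  slack <- cfg$merge_slack_s %||% 0L
  annotate <- cfg$annotate %||% TRUE
  shifts <- scenario$shifts
  files <- character()
  layout <- generate_layout(scenario)
  placement_path <- file.path(out_dir, "placement.yaml")
  write_placement(layout$placement, placement_path)
  files <- c(files, placement_path)
  histories <- list()
  for (si in shifts) {
    tag <- sprintf("%02d", si)
    if ("simulate" %in% stages) {
      mt_log("stage simulate: shift ", si, quiet = quiet)
      sim <- simulate_shift(scenario, si, layout = layout)
      raw_path <- file.path(out_dir, sprintf("raw%s.json.xz", tag))
      truth_path <- file.path(out_dir, sprintf("truth%s.json", tag))
      write_records(sim$records, raw_path)
      write_truth(sim$truth, truth_path)
      files <- c(files, raw_path, truth_path)
    }
    if ("intervals" %in% stages) {
      mt_log("stage intervals: shift ", si, quiet = quiet)
      raw <- parse_raw_records(file.path(out_dir, sprintf("raw%s.json.xz", tag)))
      iv <- build_intervals(raw, min_in = min_in, slack_s = slack, quiet = quiet)
      iv_path <- file.path(out_dir, sprintf("intervals%s.json.xz", tag))
      write_records(iv, iv_path)
      files <- c(files, iv_path)
    }
    if ("histories" %in% stages) {
      mt_log("stage histories: shift ", si, quiet = quiet)
      iv <- read_intervals(file.path(out_dir, sprintf("intervals%s.json.xz", tag)))
      hist <- impute_history(iv, shift_spec(si, scenario$first_day), quiet = quiet)
      if (annotate) {
        hist <- annotate_inroom(hist, load_placement(placement_path), quiet = quiet)
      }
      h_path <- file.path(out_dir, sprintf("histories%s.json.xz", tag))
      write_history(hist, h_path)
      files <- c(files, h_path)
      histories[[tag]] <- hist
    }
  }
  if ("summarize" %in% stages && length(histories)) {
    mt_log("stage summarize", quiet = quiet)
    counts <- mean_badge_count_per_bin(histories)
    counts_path <- file.path(out_dir, "badge_counts.csv")
    utils::write.csv(counts, counts_path, row.names = FALSE)
    files <- c(files, counts_path)
    if (annotate) {
      dw <- do.call(rbind, lapply(names(histories), function(tag) {
        d <- room_dwell_times(histories[[tag]])
        if (nrow(d)) cbind(shift = as.integer(tag), d) else NULL
      }))
      dw_path <- file.path(out_dir, "room_dwell.csv")
      utils::write.csv(dw %||% data.frame(), dw_path, row.names = FALSE)
      files <- c(files, dw_path)
    }
  }
  manifest <- list(
    package = "micutrace",
    version = as.character(utils::packageVersion("micutrace")),
    seed = scenario$seed,
    shifts = shifts,
    parameters = list(rooms = scenario$rooms,
                      contact_threshold_in = scenario$contact_threshold_in,
                      min_distance_in = min_in, merge_slack_s = slack,
                      low_cycle_s = scenario$low_cycle_s,
                      high_cycle_s = scenario$high_cycle_s),
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# ground-truth sidecar: a documented JSON array, not a paper format
write_truth <- function(truth, path) {
  arr <- lapply(seq_len(nrow(truth)), function(i) {
    list(badge_a = truth$badge_a[i], badge_b = truth$badge_b[i],
         true_start = format_badge_datetime(truth$true_start[i]),
         true_end = format_badge_datetime(truth$true_end[i]),
         min_distance_in = round(truth$min_distance_in[i], 2),
         duration_s = truth$duration_s[i])
  })
  jsonlite::write_json(arr, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname run_pipeline
#' @param path truth sidecar path written by the pipeline.
#' @return `read_truth()`: the ground-truth contact data frame.
#' @export
read_truth <- function(path) {
  arr <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(arr) == 0) {
    return(data.frame(badge_a = character(), badge_b = character(),
                      true_start = .POSIXct(numeric(), tz = .TZ),
                      true_end = .POSIXct(numeric(), tz = .TZ),
                      min_distance_in = numeric(), duration_s = numeric()))
  }
  data.frame(badge_a = arr$badge_a, badge_b = arr$badge_b,
             true_start = parse_badge_datetime(arr$true_start),
             true_end = parse_badge_datetime(arr$true_end),
             min_distance_in = arr$min_distance_in,
             duration_s = arr$duration_s)
}
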