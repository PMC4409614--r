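# End-to-end pipeline: events + roster (+ trajectories) -> networks ->
# centrality table -> level comparison, correlation tables, timelines.
# Every artifact is a plain CSV (plus GraphML for the networks) that the
# package's own readers can re-read.

observed_hour <- function(start_time, windows = default_windows()) {
  abs_start <- (windows$day - 1) * 86400 + windows$start_sec
  abs_end <- (windows$day - 1) * 86400 + windows$end_sec
  o <- order(abs_start)
  abs_start <- abs_start[o]; abs_end <- abs_end[o]
  before <- cumsum(c(0, head(abs_end - abs_start, -1)))
  hour <- rep(NA_integer_, length(start_time))
  for (i in seq_along(abs_start)) {
    inside <- start_time >= abs_start[i] & start_time < abs_end[i]
    hour[inside] <- as.integer((before[i] + start_time[inside] - abs_start[i]) %/% 3600) + 1L
  }
  hour
}

total_observed_hours <- function(windows = default_windows()) {
  as.integer(ceiling(sum(windows$end_sec - windows$start_sec) / 3600))
}

#' Timeline of the fights in one pen
#'
#' Chronologically sorted event sequence (who attacked whom, when) plus
#' per-observed-hour fight counts, the representation used to inspect the
#' decline of fighting after mixing. The observed hour counts only time
#' inside the observation windows (hour 1 = first hour after mixing; the
#' unobserved night does not advance the clock).
#'
#' @param events Fight-event tibble of a single pen (or pass `pen_id`).
#' @param pen_id Optional pen to select from a multi-pen event table.
#' @param windows Observation windows the timestamps live in.
#' @return List with `timeline` (tibble `time`, `obs_hour`, `attacker`,
#'   `victim`, `standoff`; for stand-offs the attacker/victim columns hold
#'   the unordered participants) and `hourly` (tibble `obs_hour`, `n_fights`
#'   covering every observed hour, zeros included).
#' @export
timeline_export <- function(events, pen_id = NULL, windows = default_windows()) {
  ev <- if (is.null(pen_id)) events else events[events$pen_id == pen_id, ]
  if (length(unique(ev$pen_id)) > 1) {
    abort("timeline_export expects events of a single pen",
          class = "agonet_validation_error")
  }
  ev <- ev[order(ev$start_time, ev$animal_a, ev$animal_b), ]
  hours <- observed_hour(ev$start_time, windows)
  timeline <- tibble::tibble(
    time = format_fight_time(ev$start_time),
    obs_hour = hours,
    attacker = ifelse(ev$standoff, pmin(ev$animal_a, ev$animal_b), ev$animal_a),
    victim = ifelse(ev$standoff, pmax(ev$animal_a, ev$animal_b), ev$animal_b),
    standoff = ev$standoff
  )
  all_hours <- seq_len(total_observed_hours(windows))
  hourly <- tibble::tibble(
    obs_hour = all_hours,
    n_fights = as.integer(table(factor(hours, levels = all_hours)))
  )
  list(timeline = timeline, hourly = hourly)
}

as_table_or_read <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full agonistic-network analysis
#'
#' Ties the stages together: filter events to the observation protocol,
#' build one directed weighted network per pen, compute the centrality
#' table, compare every measure across age levels (with significance
#' letters), compute within-level and consecutive-level Spearman
#' correlations, and export per-pen timelines. All artifacts are written
#' under `out_dir`:
#'
#' * `networks_edges.csv` - pooled edge list (pen_id, age_level, source,
#'   target, weight) and `networks/<level>_<pen>.graphml` per pen
#' * `centrality.csv` - the per-animal measure table
#' * `level_summary.csv` - median/range per level with letters and the
#'   Kruskal-Wallis statistics
#' * `within_level_correlations.csv`, `cross_level_correlations.csv`
#' * `timeline.csv` and `hourly_counts.csv`
#' * `run_log.txt` - seed/options and artifact checksums
#'
#' @param events,roster,trajectories Tibbles or CSV paths (trajectories may
#'   be `NULL`; the cross-level table is skipped then).
#' @param simulate Optional `synthetic_config` (or YAML path): generate the
#'   study instead of reading inputs. Exactly one of `events`/`simulate`
#'   must be given.
#' @param out_dir Output directory (created if needed).
#' @param min_duration,windows Filtering options (see [filter_events()]).
#' @param alpha Significance level for the letters.
#' @param standardized,scaling Centrality options (see
#'   [centrality_table()]).
#' @param pen_median Compare pen medians instead of pooled animals.
#' @param write_graphml_files Write one GraphML file per pen (default TRUE).
#' @return Invisibly, a list with the computed tables (`centrality`,
#'   `level_summary`, `within_level`, `cross_level`, `timeline`, `hourly`)
#'   and `paths` of the written artifacts.
#' @export
run_pipeline <- function(events = NULL, roster = NULL, trajectories = NULL,
                         simulate = NULL, out_dir,
                         min_duration = 1, windows = default_windows(),
                         alpha = 0.05, standardized = FALSE,
                         scaling = "component", pen_median = FALSE,
                         write_graphml_files = TRUE) {
  if (is.null(simulate) == is.null(events)) {
    abort("provide either input tables/paths or a simulate config, not both",
          class = "agonet_config_error")
  }
  log_lines <- character()
  push_log <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(simulate)) {
    cfg <- if (is.character(simulate)) read_config_yaml(simulate) else simulate
    study <- generate_study(cfg)
    events <- study$events
    roster <- study$roster
    trajectories <- study$trajectories
    push_log("mode: simulate (seed %d)", cfg$seed)
  } else {
    events <- as_table_or_read(events, read_events)
    roster <- as_table_or_read(roster, read_roster)
    if (!is.null(trajectories)) {
      trajectories <- as_table_or_read(trajectories, read_trajectories)
    }
    push_log("mode: observed inputs")
  }
  push_log("options: min_duration=%g alpha=%g standardized=%s scaling=%s pen_median=%s",
           min_duration, alpha, standardized, scaling, pen_median)
  push_log("weighted shortest-path convention: edge length = 1/weight")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  kept <- filter_events(events, windows = windows, min_duration = min_duration)
  push_log("events: %d read, %d retained by the observation protocol",
           nrow(events), nrow(kept))
  if (nrow(kept) == 0) {
    warn("no events left after filtering; centralities will be all zero")
    push_log("warning: no events after filtering")
  }

  nets <- build_networks(kept, roster)
  edge_tbl <- dplyr::bind_rows(lapply(nets, function(n) {
    if (!nrow(n$edges)) return(NULL)
    tibble::tibble(pen_id = n$pen_id, age_level = n$age_level,
                   source = n$edges$from, target = n$edges$to,
                   weight = n$edges$weight)
  }))
  paths$edges <- file.path(out_dir, "networks_edges.csv")
  readr::write_csv(edge_tbl, paths$edges)
  if (write_graphml_files) {
    gdir <- file.path(out_dir, "networks")
    dir.create(gdir, showWarnings = FALSE)
    for (n in nets) {
      write_graphml(n, file.path(gdir, paste0(n$age_level, "_", n$pen_id, ".graphml")))
    }
    push_log("wrote %d GraphML networks", length(nets))
  }

  records <- centrality_table(nets, standardized = standardized, scaling = scaling)
  paths$centrality <- file.path(out_dir, "centrality.csv")
  readr::write_csv(records, paths$centrality)

  level_summary <- NULL
  if (nrow(kept) > 0 && length(unique(records$age_level)) >= 2) {
    level_summary <- compare_levels(records, alpha = alpha, pen_median = pen_median)
    paths$level_summary <- file.path(out_dir, "level_summary.csv")
    readr::write_csv(level_summary, paths$level_summary)
  } else {
    push_log("warning: level comparison skipped (no events or a single level)")
  }

  within <- dplyr::bind_rows(lapply(intersect(age_levels(), unique(records$age_level)),
                                    function(lv) within_level_correlations(records, lv)))
  paths$within <- file.path(out_dir, "within_level_correlations.csv")
  readr::write_csv(within, paths$within)

  cross <- NULL
  if (!is.null(trajectories)) {
    cross <- cross_level_correlations(records, trajectories)
    paths$cross <- file.path(out_dir, "cross_level_correlations.csv")
    readr::write_csv(cross, paths$cross)
  }

  pens <- unique(kept[c("pen_id", "age_level")])
  tl_rows <- list(); hr_rows <- list()
  for (i in seq_len(nrow(pens))) {
    tl <- timeline_export(kept[kept$pen_id == pens$pen_id[i], ],
                          windows = windows)
    tl_rows[[i]] <- dplyr::mutate(tl$timeline, pen_id = pens$pen_id[i],
                                  age_level = pens$age_level[i], .before = 1)
    hr_rows[[i]] <- dplyr::mutate(tl$hourly, pen_id = pens$pen_id[i],
                                  age_level = pens$age_level[i], .before = 1)
  }
  timeline <- dplyr::bind_rows(tl_rows)
  hourly <- dplyr::bind_rows(hr_rows)
  paths$timeline <- file.path(out_dir, "timeline.csv")
  paths$hourly <- file.path(out_dir, "hourly_counts.csv")
  readr::write_csv(timeline, paths$timeline)
  readr::write_csv(hourly, paths$hourly)

  sums <- tools::md5sum(unlist(paths))
  push_log("artifact md5 checksums:")
  for (i in seq_along(sums)) {
    push_log("  %s  %s", unname(sums[i]), basename(names(sums)[i]))
  }
  paths$log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)

  invisible(list(centrality = records, level_summary = level_summary,
                 within_level = within, cross_level = cross,
                 timeline = timeline, hourly = hourly, paths = paths))
}
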