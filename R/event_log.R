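#' @useDynLib agonet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats median pchisq pt cor complete.cases rpois rnorm runif
#' @importFrom utils combn head
"_PACKAGE"

#' Age levels of the rearing sequence
#'
#' The three successive mixing situations a pig passes through: weaned pigs in
#' flatdeck pens, growing pigs in the growing stable, and gilts in the
#' breeding stable.
#'
#' @return Character vector of the level names, in rearing order.
#' @export
age_levels <- function() c("weaned", "growing", "gilt")

# ---- time representation ---------------------------------------------------
# Fight times are stored internally as seconds since 00:00:00 of day 1 (the
# mixing day); the CSV form is "D:HH:MM:SS" with D a 1-based day index, since
# the observation protocol is anchored to the mixing event, not to calendar
# dates.

#' Parse fight timestamps
#'
#' Converts `"D:HH:MM:SS"` strings (D = 1-based day since mixing) to numeric
#' seconds since 00:00:00 of day 1.
#'
#' @param x Character vector of timestamps.
#' @return Numeric vector of seconds.
#' @export
parse_fight_time <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+):([0-9]{2}):([0-9]{2}):([0-9]{2})$", x))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    abort(
      paste0("unparseable timestamp(s): ",
             paste(utils::head(x[bad], 5), collapse = ", ")),
      class = "agonet_validation_error"
    )
  }
  f <- vapply(m, function(p) {
    p <- as.numeric(p[-1])
    if (p[1] < 1 || p[2] > 23 || p[3] > 59 || p[4] > 59) return(NA_real_)
    (p[1] - 1) * 86400 + p[2] * 3600 + p[3] * 60 + p[4]
  }, numeric(1))
  if (anyNA(f)) {
    abort("timestamp field out of range (day >= 1, HH < 24, MM/SS < 60)",
          class = "agonet_validation_error")
  }
  f
}

#' Format fight timestamps
#'
#' Inverse of [parse_fight_time()].
#'
#' @param sec Numeric seconds since 00:00:00 of day 1.
#' @return Character vector `"D:HH:MM:SS"`.
#' @export
format_fight_time <- function(sec) {
  day <- sec %/% 86400 + 1
  r <- sec %% 86400
  sprintf("%d:%02d:%02d:%02d", as.integer(day),
          as.integer(r %/% 3600), as.integer((r %% 3600) %/% 60),
          as.integer(r %% 60))
}

clock_seconds <- function(x) {
  # "HH:MM" or "HH:MM:SS" -> seconds of day
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(q) {
    q <- as.numeric(q)
    if (length(q) == 2) q <- c(q, 0)
    q[1] * 3600 + q[2] * 60 + q[3]
  }, numeric(1))
}

# ---- observation windows ---------------------------------------------------

#' Construct observation windows
#'
#' An observation window is a half-open daily interval `[start, end)` during
#' which fights are scored. Windows are start-inclusive and end-exclusive so
#' that adjacent windows never double-count an event.
#'
#' @param day Integer vector of 1-based day indices.
#' @param start,end Clock times as `"HH:MM"` or `"HH:MM:SS"` strings.
#' @return A tibble with columns `day`, `start_sec`, `end_sec`.
#' @export
obs_windows <- function(day, start, end) {
  s <- clock_seconds(start)
  e <- clock_seconds(end)
  if (any(s >= e)) {
    abort("window start must precede window end", class = "agonet_validation_error")
  }
  tibble::tibble(day = as.integer(day), start_sec = s, end_sec = e)
}

#' Default observation windows
#'
#' The standard two-day post-mixing protocol: day 1 from 12:00 to 18:00
#' (mixing at noon) and day 2 from 07:00 to 18:00, 17 observed hours in
#' total. The night period 18:00-07:00 is not observed.
#'
#' @return A two-row window tibble (see [obs_windows()]).
#' @export
default_windows <- function() {
  obs_windows(day = c(1L, 2L), start = c("12:00", "07:00"),
              end = c("18:00", "18:00"))
}

# ---- event / roster / trajectory I/O --------------------------------------

EVENT_COLS <- c("pen_id", "age_level", "animal_a", "animal_b",
                "start_time", "duration_s", "standoff")

#' Assemble a fight-event table
#'
#' One row per recorded agonistic interaction. For a clear fight `animal_a`
#' is the initiator and `animal_b` the receiver; for a stand-off (initiator
#' and receiver could not be identified) the two ids are unordered
#' participants.
#'
#' @param pen_id,animal_a,animal_b Character vectors.
#' @param age_level Character vector, each element one of [age_levels()].
#' @param start_time Numeric seconds since day-1 00:00 (see
#'   [parse_fight_time()]).
#' @param duration_s Positive numeric seconds.
#' @param standoff Logical.
#' @return A validated tibble with the event columns.
#' @export
fight_events <- function(pen_id = character(), age_level = character(),
                         animal_a = character(), animal_b = character(),
                         start_time = numeric(), duration_s = numeric(),
                         standoff = logical()) {
  ev <- tibble::tibble(
    pen_id = as.character(pen_id),
    age_level = as.character(age_level),
    animal_a = as.character(animal_a),
    animal_b = as.character(animal_b),
    start_time = as.numeric(start_time),
    duration_s = as.numeric(duration_s),
    standoff = as.logical(standoff)
  )
  validate_events(ev)
  ev
}

validate_events <- function(ev) {
  bad_level <- !ev$age_level %in% age_levels()
  if (any(bad_level)) {
    abort(paste0("unknown age_level in row(s) ",
                 paste(utils::head(which(bad_level), 5), collapse = ", ")),
          class = "agonet_validation_error")
  }
  self <- ev$animal_a == ev$animal_b
  if (any(self)) {
    abort(paste0("animal_a equals animal_b (self-fight) in row(s) ",
                 paste(utils::head(which(self), 5), collapse = ", ")),
          class = "agonet_validation_error")
  }
  if (any(ev$duration_s <= 0)) {
    abort("duration_s must be positive", class = "agonet_validation_error")
  }
  invisible(ev)
}

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "agonet_schema_error")
  }
}

#' Read a fight-event log
#'
#' Reads the events CSV (columns `pen_id, age_level, animal_a, animal_b,
#' start_time, duration_s, standoff`; `start_time` as `"D:HH:MM:SS"`,
#' `standoff` as 0/1) and validates it: unknown age levels, self-fights and
#' unparseable timestamps are errors that name the offending rows.
#'
#' @param path Path to a CSV file.
#' @return A fight-event tibble in file order.
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  require_cols(df, EVENT_COLS, "events CSV")
  fight_events(
    pen_id = df$pen_id, age_level = df$age_level,
    animal_a = df$animal_a, animal_b = df$animal_b,
    start_time = if (nrow(df)) parse_fight_time(df$start_time) else numeric(),
    duration_s = as.numeric(df$duration_s),
    standoff = as.integer(df$standoff) != 0L
  )
}

#' Write a fight-event log
#'
#' Inverse of [read_events()]; `read_events(write_events(ev, p))` returns an
#' identical table.
#'
#' @param events Fight-event tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  out$start_time <- format_fight_time(out$start_time)
  out$standoff <- as.integer(out$standoff)
  readr::write_csv(out[EVENT_COLS], path)
  invisible(path)
}

#' Read a pen roster
#'
#' The roster lists every animal housed in every pen (columns `pen_id,
#' age_level, animal_id`), so that animals never involved in a fight still
#' appear as isolated nodes with zero centrality. An animal listed in two
#' different pens at the same age level is an error.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `pen_id`, `age_level`, `animal_id`.
#' @export
read_roster <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  require_cols(df, c("pen_id", "age_level", "animal_id"), "roster CSV")
  ros <- tibble::tibble(pen_id = df$pen_id, age_level = df$age_level,
                        animal_id = df$animal_id)
  validate_roster(ros)
  ros
}

validate_roster <- function(ros) {
  if (any(!ros$age_level %in% age_levels())) {
    abort("unknown age_level in roster", class = "agonet_validation_error")
  }
  key <- paste(ros$animal_id, ros$age_level, sep = "\r")
  dup <- ros[duplicated(key) | duplicated(key, fromLast = TRUE), ]
  if (nrow(dup)) {
    conf <- dplyr::distinct(dup, .data$animal_id, .data$age_level, .data$pen_id)
    n_pens <- dplyr::count(conf, .data$animal_id, .data$age_level)
    if (any(n_pens$n > 1)) {
      bad <- n_pens$animal_id[n_pens$n > 1][1]
      abort(paste0("animal ", bad, " is assigned to more than one pen at the same age level"),
            class = "agonet_validation_error")
    }
  }
  invisible(ros)
}

#' Write a pen roster
#' @param roster Roster tibble (`pen_id`, `age_level`, `animal_id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  readr::write_csv(roster[c("pen_id", "age_level", "animal_id")], path)
  invisible(path)
}

#' Read animal trajectories
#'
#' A trajectory links the same individual across age levels (columns
#' `animal_id, weaned_pen, growing_pen, gilt_pen`; an empty cell means the
#' animal was not tracked at that level, e.g. it was resold or slaughtered).
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per animal; pen columns are `NA` where the
#'   animal is absent from a level.
#' @export
read_trajectories <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  require_cols(df, c("animal_id", "weaned_pen", "growing_pen", "gilt_pen"),
               "trajectory CSV")
  if (anyDuplicated(df$animal_id)) {
    abort("duplicate animal_id in trajectory table", class = "agonet_validation_error")
  }
  tibble::as_tibble(df[c("animal_id", "weaned_pen", "growing_pen", "gilt_pen")])
}

#' Write animal trajectories
#' @param trajectories Trajectory tibble (see [read_trajectories()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(
    trajectories[c("animal_id", "weaned_pen", "growing_pen", "gilt_pen")],
    path, na = "")
  invisible(path)
}

# ---- filtering -------------------------------------------------------------

#' Filter fight events to the observation protocol
#'
#' Retains events whose start falls inside one of the observation windows
#' (start-inclusive, end-exclusive) and whose duration is at least
#' `min_duration` seconds. Aggressive contacts are only scored as agonistic
#' interactions when they last longer than a single second tick; with
#' second-resolution logging this is implemented as `duration_s >=
#' min_duration` with a default of 1 s.
#'
#' @param events Fight-event tibble.
#' @param windows Window tibble (default: [default_windows()]).
#' @param min_duration Minimum duration in seconds (default 1).
#' @return The filtered events, original order preserved. Idempotent.
#' @export
filter_events <- function(events, windows = default_windows(), min_duration = 1) {
  if (!nrow(events)) return(events)
  day <- events$start_time %/% 86400 + 1
  tod <- events$start_time %% 86400
  in_window <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(windows))) {
    in_window <- in_window |
      (day == windows$day[i] & tod >= windows$start_sec[i] & tod < windows$end_sec[i])
  }
  events[in_window & events$duration_s >= min_duration, ]
}
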