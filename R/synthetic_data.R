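# Synthetic post-mixing fight studies.
#
# The generator emulates the structure of a three-level rearing study: a
# cohort of weaned pigs is mixed into many small flatdeck pens, the
# surviving animals are re-mixed into fewer, larger growing pens, and again
# into gilt pens. Each animal carries a latent log-aggressiveness trait that
# is positively correlated across consecutive levels; its number of
# initiated fights in a pen is Poisson with a log-normal trait multiplier,
# victims are drawn uniformly among pen mates, fight times follow the
# observation windows with an optional exponential decline after mixing,
# and a configurable fraction of fights is recorded as stand-offs.
#
# Default fight intensities are anchored to the reported per-level medians
# of total fight involvement (12 / 5 / 5 for weaned / growing / gilt): with
# initiated counts Poisson(m * M_i), M_i log-normal with unit mean and
# median exp(-sd^2/2), and received counts averaging m, the median
# involvement is about m * (1 + exp(-sd^2/2)) = 1.73 m at sd = 0.8, giving
# m of 7 and 2.9 - a weaned intensity about 2.4x the older levels.

#' Configuration of a synthetic fight study
#'
#' Defaults emulate the standard study design: 65 weaned / 24 growing / 12
#' gilt groups with group sizes 6-11 / 20-25 / 18-29, a 17-hour two-day
#' observation window, roughly twice the per-animal fight intensity in
#' weaned pigs compared to the older levels, no within-window decline of
#' fighting in weaned pigs but a clear first-hours peak in growing pigs and
#' gilts, and a modest positive carry-over of individual aggressiveness
#' from one mixing to the next.
#'
#' @param seed Integer RNG seed; the whole study is reproducible from it.
#' @param groups_per_level Named integer vector (weaned, growing, gilt).
#' @param group_size_ranges Named list of `c(min, max)` group sizes.
#' @param mean_fights_per_animal Named numeric vector: expected initiated
#'   fights per animal over the observation period, per level.
#' @param temporal_decay_rate Named numeric vector: exponential decline rate
#'   of fighting per hour since mixing (0 = uniform over the windows).
#' @param trait_sd Standard deviation of the latent log-aggressiveness
#'   trait; the per-animal fight-rate multiplier is
#'   `exp(trait_sd * z - trait_sd^2 / 2)` with `z ~ N(0, 1)` (mean 1, so
#'   `mean_fights_per_animal` stays the level mean).
#' @param cross_level_trait_correlation Correlation of the latent trait
#'   between consecutive levels, in `[-1, 1]`.
#' @param standoff_probability Probability that a fight is recorded with
#'   unclear initiator (stand-off).
#' @param observation_windows Window tibble (default [default_windows()]).
#' @param duration_meanlog,duration_sdlog Log-normal parameters of fight
#'   duration in seconds (rounded, floored at 1 s).
#' @param victim_bias Targeted-opponent strength: victims are drawn with
#'   probability proportional to `exp(victim_bias * trait)`, so positive
#'   values concentrate received fights on high-trait animals. 0 (the
#'   default) keeps the uniform victim choice.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    groups_per_level = c(weaned = 65L, growing = 24L, gilt = 12L),
    group_size_ranges = list(weaned = c(6L, 11L), growing = c(20L, 25L),
                             gilt = c(18L, 29L)),
    mean_fights_per_animal = c(weaned = 7, growing = 2.9, gilt = 2.9),
    temporal_decay_rate = c(weaned = 0, growing = 0.15, gilt = 0.15),
    trait_sd = 0.8,
    cross_level_trait_correlation = 0.3,
    standoff_probability = 0.1,
    observation_windows = default_windows(),
    duration_meanlog = log(15),
    duration_sdlog = 0.9,
    victim_bias = 0) {
  cfg <- list(
    seed = as.integer(seed),
    groups_per_level = groups_per_level[age_levels()],
    group_size_ranges = group_size_ranges[age_levels()],
    mean_fights_per_animal = mean_fights_per_animal[age_levels()],
    temporal_decay_rate = temporal_decay_rate[age_levels()],
    trait_sd = trait_sd,
    cross_level_trait_correlation = cross_level_trait_correlation,
    standoff_probability = standoff_probability,
    observation_windows = observation_windows,
    duration_meanlog = duration_meanlog,
    duration_sdlog = duration_sdlog,
    victim_bias = victim_bias
  )
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  if (anyNA(cfg$groups_per_level) || any(cfg$groups_per_level < 1)) {
    abort("groups_per_level must be positive for all three levels",
          class = "agonet_config_error")
  }
  for (lv in age_levels()) {
    r <- cfg$group_size_ranges[[lv]]
    if (length(r) != 2 || r[1] < 2 || r[1] > r[2]) {
      abort(paste0("invalid group size range for ", lv),
            class = "agonet_config_error")
    }
  }
  if (anyNA(cfg$mean_fights_per_animal) || any(cfg$mean_fights_per_animal < 0)) {
    abort("mean_fights_per_animal must be non-negative", class = "agonet_config_error")
  }
  if (anyNA(cfg$temporal_decay_rate) || any(cfg$temporal_decay_rate < 0)) {
    abort("temporal_decay_rate must be non-negative", class = "agonet_config_error")
  }
  if (cfg$trait_sd < 0) {
    abort("trait_sd must be non-negative", class = "agonet_config_error")
  }
  if (abs(cfg$cross_level_trait_correlation) > 1) {
    abort("cross_level_trait_correlation must be in [-1, 1]",
          class = "agonet_config_error")
  }
  if (cfg$standoff_probability < 0 || cfg$standoff_probability > 1) {
    abort("standoff_probability must be in [0, 1]", class = "agonet_config_error")
  }
  invisible(cfg)
}

#' Read a synthetic-study configuration from YAML
#'
#' Field names mirror the arguments of [synthetic_config()];
#' `observation_windows` is a list of `{day, start, end}` entries with clock
#' times as strings. Absent fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `synthetic_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scalar <- c("seed", "trait_sd", "cross_level_trait_correlation",
              "standoff_probability", "duration_meanlog", "duration_sdlog",
              "victim_bias")
  for (f in scalar) if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  named <- c("groups_per_level", "mean_fights_per_animal", "temporal_decay_rate")
  for (f in named) if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])[age_levels()]
  if (!is.null(y$group_size_ranges)) {
    args$group_size_ranges <- lapply(y$group_size_ranges, as.integer)[age_levels()]
  }
  if (!is.null(y$observation_windows)) {
    w <- y$observation_windows
    args$observation_windows <- obs_windows(
      day = vapply(w, `[[`, numeric(1), "day"),
      start = vapply(w, `[[`, character(1), "start"),
      end = vapply(w, `[[`, character(1), "end"))
  }
  do.call(synthetic_config, args)
}

# hours since mixing covered by each window; mixing is anchored at the start
# of the first window (observation begins directly after mixing)
window_segments <- function(windows) {
  abs_start <- (windows$day - 1) * 86400 + windows$start_sec
  abs_end <- (windows$day - 1) * 86400 + windows$end_sec
  mix <- min(abs_start)
  list(a = (abs_start - mix) / 3600, b = (abs_end - mix) / 3600, mix_abs = mix)
}

# inverse-CDF sampling of fight times (absolute seconds, floored to second
# resolution) with density proportional to exp(-rate * hours_since_mixing)
# restricted to the observation windows
sample_fight_times <- function(n, rate, windows) {
  seg <- window_segments(windows)
  mass <- if (rate > 0) (exp(-rate * seg$a) - exp(-rate * seg$b)) / rate else seg$b - seg$a
  j <- sample.int(length(mass), n, replace = TRUE, prob = mass)
  u <- runif(n)
  t_h <- if (rate > 0) {
    fa <- exp(-rate * seg$a[j]); fb <- exp(-rate * seg$b[j])
    -log(fa - u * (fa - fb)) / rate
  } else {
    seg$a[j] + u * (seg$b[j] - seg$a[j])
  }
  floor(seg$mix_abs + t_h * 3600)
}

#' Generate the fight log of a single pen
#'
#' Uses the current RNG state (seed it with `set.seed()` for
#' reproducibility). Each animal initiates a Poisson number of fights with
#' mean `mean_fights` times its trait multiplier; victims are uniform among
#' pen mates.
#'
#' @param size Number of animals (>= 2), or supply `animal_ids`.
#' @param mean_fights Expected initiated fights per animal.
#' @param decay Exponential decline rate of fighting per hour since mixing.
#' @param standoff_p Stand-off probability per fight.
#' @param windows Observation windows.
#' @param pen_id,age_level Identifiers stamped on the events.
#' @param animal_ids Optional explicit ids (length = size).
#' @param traits Optional latent trait z-scores (length = size); drawn
#'   N(0, 1) when missing.
#' @param trait_sd Trait dispersion (see [synthetic_config()]).
#' @param duration_meanlog,duration_sdlog Fight-duration log-normal
#'   parameters.
#' @param victim_bias Targeted-opponent strength (see [synthetic_config()]).
#' @return A fight-event tibble, chronologically sorted.
#' @export
generate_pen <- function(size, mean_fights, decay = 0, standoff_p = 0,
                         windows = default_windows(),
                         pen_id = "pen1", age_level = "weaned",
                         animal_ids = NULL, traits = NULL, trait_sd = 0.8,
                         duration_meanlog = log(15), duration_sdlog = 0.9,
                         victim_bias = 0) {
  if (is.null(animal_ids)) {
    if (size < 2) abort("pen size must be >= 2", class = "agonet_config_error")
    animal_ids <- sprintf("%s_p%02d", pen_id, seq_len(size))
  }
  size <- length(animal_ids)
  if (size < 2) abort("pen size must be >= 2", class = "agonet_config_error")
  if (is.null(traits)) traits <- rnorm(size)
  lambda <- mean_fights * exp(trait_sd * traits - trait_sd^2 / 2)
  n_i <- rpois(size, lambda)
  total <- sum(n_i)
  if (total == 0) {
    return(fight_events())
  }
  init_idx <- rep(seq_len(size), n_i)
  if (victim_bias == 0) {
    off <- sample.int(size - 1, total, replace = TRUE)
    vic_idx <- off + (off >= init_idx)   # uniform over the size-1 pen mates
  } else {
    # targeted opponents: victim probability proportional to
    # exp(victim_bias * trait) among the pen mates
    prob <- exp(victim_bias * traits)
    vic_idx <- vapply(init_idx, function(a) {
      p <- prob; p[a] <- 0
      sample.int(size, 1, prob = p)
    }, integer(1))
  }
  initiator <- animal_ids[init_idx]
  victim <- animal_ids[vic_idx]
  ev <- fight_events(
    pen_id = rep(pen_id, total),
    age_level = rep(age_level, total),
    animal_a = initiator,
    animal_b = victim,
    start_time = sample_fight_times(total, decay, windows),
    duration_s = pmax(1, round(stats::rlnorm(total, duration_meanlog, duration_sdlog))),
    standoff = runif(total) < standoff_p
  )
  ev[order(ev$start_time, ev$animal_a, ev$animal_b), ]
}

# draw group sizes within [min, max] under a total-animal budget; sizes are
# decremented from the largest pens when the draw overshoots the budget
draw_group_sizes <- function(n_groups, range, budget = Inf) {
  if (n_groups * range[1] > budget) {
    abort(sprintf("infeasible roster partition: %d groups of >= %d animals exceed the %d available",
                  n_groups, range[1], as.integer(budget)),
          class = "agonet_config_error")
  }
  sizes <- sample(seq(range[1], range[2]), n_groups, replace = TRUE)
  while (sum(sizes) > budget) {
    k <- which.max(sizes)
    sizes[k] <- sizes[k] - 1L
  }
  sizes
}

#' Generate a full synthetic three-level study
#'
#' Produces rosters, animal trajectories, fight events, and the latent
#' traits for one complete study: the weaned cohort is partitioned into
#' pens, a subset of animals advances to the growing level (the rest are
#' "resold"), and a further subset advances to the gilt level, each time
#' re-partitioned into new pens. Latent traits evolve between consecutive
#' levels as a stationary AR(1) process with the configured correlation.
#' Fully reproducible: the same config (including seed) yields an identical
#' study; the single random stream is consumed in deterministic pen order.
#'
#' @param config A `synthetic_config`.
#' @return List with elements `roster`, `trajectories`, `events` (tibbles in
#'   the package's standard schemas) and `traits` (tibble `animal_id`,
#'   `age_level`, `trait` of the latent z-scores, for calibration checks).
#' @export
generate_study <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  rho <- config$cross_level_trait_correlation
  pen_prefix <- c(weaned = "w", growing = "g", gilt = "b")

  sizes_w <- draw_group_sizes(config$groups_per_level[["weaned"]],
                              config$group_size_ranges[["weaned"]])
  n_total <- sum(sizes_w)
  ids <- sprintf("p%04d", seq_len(n_total))

  roster <- list(); events <- list(); traits_out <- list()
  traj <- tibble::tibble(animal_id = ids,
                         weaned_pen = NA_character_,
                         growing_pen = NA_character_,
                         gilt_pen = NA_character_)
  cur_ids <- ids
  cur_traits <- rnorm(n_total)

  for (li in seq_along(age_levels())) {
    lv <- age_levels()[li]
    sizes <- if (li == 1) sizes_w else
      draw_group_sizes(config$groups_per_level[[lv]],
                       config$group_size_ranges[[lv]],
                       budget = length(cur_ids))
    if (li > 1) {
      keep <- sort(sample.int(length(cur_ids), sum(sizes)))
      cur_ids <- cur_ids[keep]
      cur_traits <- rho * cur_traits[keep] +
        sqrt(1 - rho^2) * rnorm(length(keep))
    }
    perm <- sample.int(length(cur_ids))
    pen_of <- rep(seq_along(sizes), sizes)
    pen_ids <- sprintf("%s%03d", pen_prefix[[lv]], seq_along(sizes))
    assign_pen <- character(length(cur_ids))
    assign_pen[perm] <- pen_ids[pen_of]
    traj[[paste0(lv, "_pen")]][match(cur_ids, traj$animal_id)] <- assign_pen
    roster[[lv]] <- tibble::tibble(pen_id = assign_pen, age_level = lv,
                                   animal_id = cur_ids) |>
      dplyr::arrange(.data$pen_id, .data$animal_id)
    traits_out[[lv]] <- tibble::tibble(animal_id = cur_ids, age_level = lv,
                                       trait = cur_traits)
    for (p in pen_ids) {
      members <- cur_ids[assign_pen == p]
      events[[paste(lv, p)]] <- generate_pen(
        size = length(members),
        mean_fights = config$mean_fights_per_animal[[lv]],
        decay = config$temporal_decay_rate[[lv]],
        standoff_p = config$standoff_probability,
        windows = config$observation_windows,
        pen_id = p, age_level = lv,
        animal_ids = members,
        traits = cur_traits[assign_pen == p],
        trait_sd = config$trait_sd,
        duration_meanlog = config$duration_meanlog,
        duration_sdlog = config$duration_sdlog,
        victim_bias = config$victim_bias
      )
    }
  }
  list(
    roster = dplyr::bind_rows(roster),
    trajectories = traj,
    events = dplyr::bind_rows(events),
    traits = dplyr::bind_rows(traits_out)
  )
}
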