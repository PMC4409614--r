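# Small fixtures built in code.

noon <- function(h = 12, m = 0, s = 0, day = 1) {
  (day - 1) * 86400 + h * 3600 + m * 60 + s
}

make_events <- function(a, b, standoff = FALSE, pen = "p1", level = "weaned",
                        time = noon(), duration = 5) {
  k <- max(length(a), length(b))
  fight_events(
    pen_id = rep_len(pen, k), age_level = rep_len(level, k),
    animal_a = rep_len(a, k), animal_b = rep_len(b, k),
    start_time = rep_len(time, k), duration_s = rep_len(duration, k),
    standoff = rep_len(standoff, k)
  )
}

make_roster <- function(animals, pen = "p1", level = "weaned") {
  tibble::tibble(pen_id = pen, age_level = level, animal_id = animals)
}

# a study small enough for unit tests but with all three levels; the group
# counts guarantee a feasible roster partition for every draw
tiny_config <- function(seed = 7, ...) {
  synthetic_config(
    seed = seed,
    groups_per_level = c(weaned = 10L, growing = 2L, gilt = 1L),
    ...
  )
}
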