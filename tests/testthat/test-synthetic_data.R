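test_that("a study is byte-identical when regenerated from the same seed", {
  s1 <- generate_study(tiny_config(seed = 42))
  s2 <- generate_study(tiny_config(seed = 42))
  expect_identical(s1, s2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_events(s1$events, p1)
  write_events(s2$events, p2)
  expect_identical(readLines(p1), readLines(p2))
  s3 <- generate_study(tiny_config(seed = 43))
  expect_false(identical(s1$events, s3$events))
})

test_that("zero fight intensity yields an empty log and all-zero centralities", {
  cfg <- tiny_config(mean_fights_per_animal = c(weaned = 0, growing = 0, gilt = 0))
  st <- generate_study(cfg)
  expect_equal(nrow(st$events), 0)
  rec <- centrality_table(build_networks(st$events, st$roster))
  expect_equal(nrow(rec), nrow(st$roster))
  expect_true(all(rec[MEASURE_COLS] == 0))
})

test_that("stand-off flagging follows the configured probability", {
  set.seed(77)
  all_so <- generate_pen(10, mean_fights = 5, standoff_p = 1)
  expect_true(all(all_so$standoff))
  none <- generate_pen(10, mean_fights = 5, standoff_p = 0)
  expect_false(any(none$standoff))

  big <- generate_pen(2, mean_fights = 500, standoff_p = 0.1, trait_sd = 0)
  expect_gt(nrow(big), 800)
  frac <- mean(big$standoff)
  expect_gt(frac, 0.07)  # 3 sigma around 0.1 at ~1000 events
  expect_lt(frac, 0.13)
})

test_that("victim bias concentrates received fights on high-trait animals", {
  set.seed(91)
  traits <- c(3, rep(-1, 9))   # one clearly dominant trait
  biased <- generate_pen(10, mean_fights = 20, traits = traits,
                         trait_sd = 0, victim_bias = 2)
  uniform <- generate_pen(10, mean_fights = 20, traits = traits,
                          trait_sd = 0, victim_bias = 0)
  top <- "pen1_p01"
  share <- function(ev) mean(ev$animal_b == top)
  expect_gt(share(biased), share(uniform))
  expect_gt(share(biased), 0.5)
})

test_that("a two-animal pen fights only within itself and rejects size < 2", {
  set.seed(14)
  ev <- generate_pen(2, mean_fights = 5)
  expect_setequal(unique(c(ev$animal_a, ev$animal_b)),
                  c("pen1_p01", "pen1_p02"))
  expect_error(generate_pen(1, mean_fights = 5), class = "agonet_config_error")
})

test_that("generated event times always lie inside the observation windows", {
  cfg <- tiny_config(seed = 3)
  st <- generate_study(cfg)
  expect_identical(filter_events(st$events, cfg$observation_windows), st$events)
})

test_that("temporal decay concentrates fights in the first six hours", {
  set.seed(23)
  first_frac <- matrix(NA_real_, 100, 3)
  for (r in 1:100) {
    ev <- generate_pen(22, mean_fights = 3, decay = 0.15, standoff_p = 0.1,
                       pen_id = "g1", age_level = "growing")
    tl <- timeline_export(ev)
    blocks <- split(tl$hourly$n_fights, ceiling(tl$hourly$obs_hour / 6))
    first_frac[r, ] <- vapply(blocks, sum, numeric(1)) / nrow(ev)
  }
  means <- colMeans(first_frac)
  expect_gt(means[1], means[2])
  expect_gt(means[1], means[3])

  # without decay the 6-hour block shares are proportional to block length
  set.seed(24)
  flat <- replicate(50, {
    ev <- generate_pen(10, mean_fights = 5, decay = 0)
    tl <- timeline_export(ev)
    blocks <- split(tl$hourly$n_fights, ceiling(tl$hourly$obs_hour / 6))
    vapply(blocks, sum, numeric(1)) / nrow(ev)
  })
  expect_equal(unname(rowMeans(flat)), c(6, 6, 5) / 17, tolerance = 0.1)
})

test_that("rosters respect group sizes, budgets, and trajectory consistency", {
  cfg <- tiny_config(seed = 11)
  st <- generate_study(cfg)
  sizes <- table(paste(st$roster$age_level, st$roster$pen_id))
  for (lv in age_levels()) {
    r <- cfg$group_size_ranges[[lv]]
    lv_sizes <- sizes[grep(paste0("^", lv), names(sizes))]
    expect_equal(length(lv_sizes), unname(cfg$groups_per_level[[lv]]))
    expect_true(all(lv_sizes >= r[1] & lv_sizes <= r[2]))
  }
  # every roster entry matches the trajectory placement
  for (lv in age_levels()) {
    ros <- st$roster[st$roster$age_level == lv, ]
    tr_pen <- st$trajectories[[paste0(lv, "_pen")]][
      match(ros$animal_id, st$trajectories$animal_id)]
    expect_identical(ros$pen_id, tr_pen)
  }
  # gilts are a subset of growing animals, which are a subset of weaned
  ids <- lapply(age_levels(), function(lv)
    st$roster$animal_id[st$roster$age_level == lv])
  expect_true(all(ids[[2]] %in% ids[[1]]))
  expect_true(all(ids[[3]] %in% ids[[2]]))

  expect_error(
    generate_study(synthetic_config(
      groups_per_level = c(weaned = 2L, growing = 2L, gilt = 1L))),
    class = "agonet_config_error")
})

test_that("YAML configs mirror the constructor arguments", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5",
    "groups_per_level: {weaned: 4, growing: 1, gilt: 1}",
    "group_size_ranges: {weaned: [8, 10], growing: [20, 25], gilt: [18, 20]}",
    "mean_fights_per_animal: {weaned: 6, growing: 3, gilt: 3}",
    "standoff_probability: 0.2",
    "observation_windows:",
    "  - {day: 1, start: \"12:00\", end: \"18:00\"}",
    "  - {day: 2, start: \"07:00\", end: \"18:00\"}"
  ), path)
  cfg <- read_config_yaml(path)
  expect_equal(cfg$seed, 5L)
  expect_equal(unname(cfg$groups_per_level), c(4, 1, 1))
  expect_equal(cfg$standoff_probability, 0.2)
  expect_equal(cfg$observation_windows, default_windows())
  expect_identical(generate_study(cfg), generate_study(cfg))
})
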