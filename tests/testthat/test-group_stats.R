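test_that("Kruskal-Wallis reproduces hand-ranked statistics and edge cases", {
  kw <- kruskal_wallis(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  # ranks 1..6, group mean ranks 1.5 / 3.5 / 5.5
  expect_equal(kw$H, 12 / 42 * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2) - 21,
               tolerance = 1e-12)
  expect_equal(kw$H, 4.5714, tolerance = 1e-4)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(kw$H, 2, lower.tail = FALSE))

  same <- kruskal_wallis(list(a = c(5, 5), b = c(5, 5), c = c(5, 5)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  expect_error(kruskal_wallis(list(a = 1:3)), class = "agonet_validation_error")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric())),
               class = "agonet_validation_error")
})

test_that("H is invariant under monotone transforms and matches the oracle formula", {
  groups <- list(a = c(1, 2, 2), b = c(3, 4), c = c(2, 6, 7, 7))
  h <- kruskal_wallis(groups)$H
  expect_equal(h, oracle_kw_H(groups), tolerance = 1e-12)
  trans <- lapply(groups, function(g) exp(g) + 1)
  expect_equal(kruskal_wallis(trans)$H, h, tolerance = 1e-12)
})

test_that("the statistic agrees with the exact enumeration oracle for N <= 8", {
  cases <- list(
    list(values = c(1, 2, 3, 4, 5, 6), sizes = c(2, 2, 2)),
    list(values = c(1, 1, 2, 2, 3, 3, 4), sizes = c(3, 2, 2)),
    list(values = c(0, 0, 0, 1, 1, 2, 5, 5), sizes = c(3, 3, 2))
  )
  for (cs in cases) {
    assignments <- enumerate_assignments(cs$values, cs$sizes)
    h_impl <- vapply(assignments, function(g) kruskal_wallis(g)$H, numeric(1))
    h_oracle <- vapply(assignments, oracle_kw_H, numeric(1))
    expect_equal(h_impl, h_oracle, tolerance = 1e-10)
    # the observed H sits inside the exact null distribution's support
    expect_true(all(h_impl >= 0))
  }
})

test_that("Spearman handles monotone, tied, and degenerate inputs", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  tie <- spearman_cor(c(1, 2, 3), c(1, 1, 2))
  expect_equal(tie$rho, 0.8660254, tolerance = 1e-6)
  expect_equal(tie$rho, cor(c(1, 2, 3), c(1.5, 1.5, 3)) , tolerance = 1e-12)

  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)          # monotone invariance
  expect_equal(spearman_cor(x, -y)$rho, -base$rho)             # antisymmetry
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(base$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(base$p_value, ref$p.value, tolerance = 1e-10)

  expect_equal(spearman_cor(c(1, 1, 1), c(1, 2, 3))$note, "zero_variance")
  expect_equal(spearman_cor(c(1, 2), c(3, 4))$note, "low_n")
  expect_error(spearman_cor(1:3, 1:4), class = "agonet_validation_error")
})

test_that("significance letters partition groups by pairwise tests", {
  set.seed(9)
  hi <- rnorm(40, 10); lo1 <- rnorm(40, 0); lo2 <- rnorm(40, 0.1)
  expect_equal(unname(assign_letters(list(w = hi, g = lo1, b = lo2))),
               c("a", "b", "b"))
  expect_equal(unname(assign_letters(list(w = lo1, g = lo2, b = lo1 + 0.05))),
               c("a", "a", "a"))
  expect_equal(unname(assign_letters(list(a = rnorm(40, 0), b = rnorm(40, 5),
                                          c = rnorm(40, 10)))),
               c("a", "b", "c"))
})

test_that("intransitive differences yield shared multi-letter labels", {
  # fixed draws where lo differs from hi but mid overlaps both
  lo <- c(1.21, 0.12, 0.15, 2.47, -1.36, 0.14, 0.72, -1.05, -0.41, -0.45, -0.43, -0.13)
  mid <- c(-0.18, 0.74, 1.11, -0.36, -0.27, -0.12, 2.35, 2.39, 0.88, 2.78, -0.73, 2.02)
  hi <- c(1.58, 1.44, 1.49, 1.05, 3.42, 0.73, 1.69, 1.92, 1.56, 1.9, 1.54, 3.42)
  expect_gt(kruskal_wallis(list(lo, mid))$p_value, 0.05)
  expect_gt(kruskal_wallis(list(mid, hi))$p_value, 0.05)
  expect_lt(kruskal_wallis(list(lo, hi))$p_value, 0.05)
  expect_equal(unname(assign_letters(list(lo = lo, mid = mid, hi = hi))),
               c("a", "ab", "b"))
})

test_that("letter partition is consistent with the pairwise tests", {
  set.seed(31)
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i) rnorm(15, mean = runif(1, 0, 2)))
    names(groups) <- c("x", "y", "z")
    lab <- assign_letters(groups)
    if (kruskal_wallis(groups)$p_value >= 0.05) {
      expect_true(all(lab == "a"))
      next
    }
    pairs <- combn(3, 2)
    for (c in seq_len(ncol(pairs))) {
      i <- pairs[1, c]; j <- pairs[2, c]
      shares <- any(strsplit(lab[i], "")[[1]] %in% strsplit(lab[j], "")[[1]])
      differs <- kruskal_wallis(groups[c(i, j)])$p_value < 0.05
      expect_identical(shares, !differs)
    }
  }
})

test_that("within-level correlations recover exact dependencies and flag low n", {
  rec <- tibble::tibble(
    animal_id = sprintf("a%02d", 1:30), pen_id = "p1", age_level = "weaned",
    n_pen = 30
  )
  set.seed(5)
  for (m in MEASURE_COLS) rec[[m]] <- runif(30)
  rec$degree_weighted <- 2 * rec$degree_binary
  out <- within_level_correlations(rec, "weaned")
  row <- out[out$var1 == "degree_binary" & out$var2 == "degree_weighted", ]
  expect_equal(row$rho, 1)

  tiny <- rec[1:2, ]
  flagged <- within_level_correlations(tiny, "weaned")
  expect_true(all(flagged$note == "low_n"))
})

test_that("cross-level correlations pair animals through trajectories", {
  ids <- sprintf("a%02d", 1:12)
  set.seed(6)
  base <- runif(12)
  rec <- dplyr::bind_rows(lapply(c("weaned", "growing", "gilt"), function(lv) {
    r <- tibble::tibble(animal_id = ids, pen_id = "x", age_level = lv, n_pen = 12)
    for (m in MEASURE_COLS) r[[m]] <- base   # identical values at every level
    r
  }))
  traj <- tibble::tibble(animal_id = ids, weaned_pen = "x",
                         growing_pen = "x", gilt_pen = "x")
  traj$gilt_pen[1:3] <- NA   # these animals leave the study after growing
  out <- cross_level_correlations(rec, traj, measures = "out_degree_binary")
  expect_equal(nrow(out), 2)
  expect_equal(out$rho, c(1, 1))
  expect_equal(out$n, c(12, 9))
})
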