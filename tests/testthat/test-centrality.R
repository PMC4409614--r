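roster_n <- function(k) make_roster(LETTERS[seq_len(k)])

path_net <- build_network(make_events(c("A", "B"), c("B", "C")), roster_n(3))

test_that("betweenness matches hand-enumerated paths on canonical graphs", {
  # directed path A -> B -> C: B carries the single A -> C shortest path
  b <- betweenness_centrality(path_net)
  expect_equal(unname(b), c(0, 0.5, 0))

  # complete directed graph: every pair adjacent, nobody in between
  cd <- expand.grid(a = LETTERS[1:4], b = LETTERS[1:4], stringsAsFactors = FALSE)
  cd <- cd[cd$a != cd$b, ]
  complete <- build_network(make_events(cd$a, cd$b), roster_n(4))
  expect_equal(max(betweenness_centrality(complete)), 0)
  expect_equal(max(betweenness_centrality(complete, weighted = TRUE)), 0)

  # uniform weights: weighted equals binary
  net <- build_network(make_events(c("A", "A", "B", "C"), c("B", "C", "D", "D")),
                       roster_n(4))
  net$edges$weight <- rep(2, nrow(net$edges))
  expect_equal(betweenness_centrality(net, weighted = TRUE),
               betweenness_centrality(net, weighted = FALSE))

  # fewer than three animals: defined as all zero
  two <- build_network(make_events("A", "B"), roster_n(2))
  expect_equal(unname(betweenness_centrality(two)), c(0, 0))
})

test_that("closeness handles direction, weights, and disconnection", {
  # out-star: center reaches all three leaves at distance 1, leaves reach nobody
  star <- build_network(make_events("A", c("B", "C", "D")), roster_n(4))
  oc <- closeness_centrality(star, "out")
  expect_equal(unname(oc), c(1, 0, 0, 0))
  ic <- closeness_centrality(star, "in")
  expect_equal(unname(ic[1]), 0)
  expect_equal(unname(ic["B"]), (1 / 3) * 1)

  # two nodes, one edge of weight 2: weighted distance 0.5, closeness 2 (> 1)
  two <- build_network(make_events(c("A", "A"), "B"), roster_n(2))
  expect_equal(unname(closeness_centrality(two, "out", weighted = TRUE)["A"]), 2)

  # n = 4 with a single edge: component scaling gives (1/3) * (1/1)
  one_edge <- build_network(make_events("A", "B"), roster_n(4))
  expect_equal(unname(closeness_centrality(one_edge, "out")["A"]), 1 / 3)
  expect_equal(unname(closeness_centrality(one_edge, "out", scaling = "off")["A"]), 1)
  expect_equal(unname(closeness_centrality(one_edge, "out")["C"]), 0)
})

test_that("degree counts opponents (binary) and fight weights (weighted)", {
  net <- build_network(make_events("A", c("B", "C")), roster_n(3))
  expect_equal(unname(degree_centrality(net, "out")["A"]), 2)
  expect_equal(unname(degree_centrality(net, "in")["A"]), 0)

  ev <- dplyr::bind_rows(make_events("A", "B"),
                         make_events("B", "C", standoff = TRUE))
  net2 <- build_network(ev, roster_n(3))
  expect_equal(unname(degree_centrality(net2, "total", weighted = TRUE)["B"]), 2)
  expect_equal(unname(degree_centrality(net2, "total", weighted = FALSE)["B"]), 2)
  # reciprocal dyad counts as one opponent
  rec <- build_network(make_events(c("A", "B"), c("B", "A")), roster_n(3))
  expect_equal(unname(degree_centrality(rec, "total")["A"]), 1)

  for (m in c("total", "in", "out")) {
    expect_equal(unname(degree_centrality(build_network(make_events("A", "B"),
                                                        roster_n(3)), m)["C"]), 0)
  }
  expect_equal(unname(degree_centrality(net, "out", standardized = TRUE)["A"]), 1)
})

test_that("betweenness and closeness match the brute-force oracle on random graphs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:7, 1)
    net <- random_pen_network(n, p = runif(1, 0.15, 0.6))
    a <- net_arrays(net)
    for (weighted in c(FALSE, TRUE)) {
      len <- if (weighted) 1 / a$w else rep(1, length(a$w))
      sp <- oracle_shortest_paths(a$n, a$from, a$to, len)
      expect_equal(unname(betweenness_centrality(net, weighted)),
                   oracle_betweenness(a$n, a$from, a$to, len),
                   tolerance = 1e-9)
      oc <- vapply(seq_len(a$n), function(i)
        oracle_closeness(sp$dist[i, -i], a$n), numeric(1))
      ic <- vapply(seq_len(a$n), function(i)
        oracle_closeness(sp$dist[-i, i], a$n), numeric(1))
      expect_equal(unname(closeness_centrality(net, "out", weighted)), oc,
                   tolerance = 1e-9)
      expect_equal(unname(closeness_centrality(net, "in", weighted)), ic,
                   tolerance = 1e-9)
    }
  }
})

test_that("binary measures are scale-invariant and weighted closeness scales linearly", {
  set.seed(55)
  net <- random_pen_network(6, p = 0.5)
  k <- 3
  scaled <- net
  scaled$edges$weight <- net$edges$weight * k
  expect_equal(betweenness_centrality(scaled, FALSE), betweenness_centrality(net, FALSE))
  expect_equal(degree_centrality(scaled, "total", FALSE), degree_centrality(net, "total", FALSE))
  expect_equal(closeness_centrality(scaled, "out", weighted = TRUE),
               k * closeness_centrality(net, "out", weighted = TRUE))
  expect_equal(betweenness_centrality(scaled, TRUE), betweenness_centrality(net, TRUE))

  # adding an edge never decreases binary degree
  ev <- make_events(c("A", "B"), c("B", "C"))
  before <- degree_centrality(build_network(ev, roster_n(4)), "total")
  after <- degree_centrality(build_network(
    dplyr::bind_rows(ev, make_events("C", "D")), roster_n(4)), "total")
  expect_true(all(after >= before))
})

test_that("the centrality table covers all animals, measures, and zero rows", {
  ev <- dplyr::bind_rows(make_events("A", "B"),
                         make_events("B", "C", standoff = TRUE))
  tab <- centrality_table(list(build_network(ev, roster_n(3))))
  expect_equal(nrow(tab), 3)
  expect_true(all(MEASURE_COLS %in% names(tab)))
  expect_equal(tab$degree_weighted[tab$animal_id == "B"], 2)
  expect_equal(tab$degree_binary[tab$animal_id == "B"], 2)

  empty <- centrality_table(list(build_network(fight_events(), roster_n(4))))
  expect_equal(nrow(empty), 4)
  expect_true(all(empty[MEASURE_COLS] == 0))
})
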