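# Centrality measures on pen fight networks.
#
# All measures come in a binary and a weighted variant. The weighted variant
# treats the fight frequency w of a link as closeness between the opponents:
# the shortest-path length of an edge is 1/w, so frequently fighting animals
# are a short "distance" apart. This is the convention under which weighted
# closeness can exceed 1 while normalized betweenness stays in [0, 1].
#
# The shortest-path kernels live in src/centrality.cpp; everything here is
# integer-indexed bookkeeping around them, kept in base R because the table
# is assembled for a hundred pens at a time.

# integer edge arrays of the positive-weight edges; undirected networks are
# expanded to two opposite arcs for the path kernels
edge_ints <- function(net) {
  keep <- net$edges$weight > 0
  i <- match(net$edges$from[keep], net$nodes)
  j <- match(net$edges$to[keep], net$nodes)
  w <- net$edges$weight[keep]
  if (!net$directed) {
    tmp <- i
    i <- c(i, j); j <- c(j, tmp); w <- c(w, w)
  }
  list(n = length(net$nodes), i = i, j = j, w = w)
}

# collapse directed integer arcs into undirected dyads, summing the two
# directional weights
undirect_ints <- function(e) {
  lo <- pmin(e$i, e$j); hi <- pmax(e$i, e$j)
  key <- (lo - 1) * e$n + hi
  agg <- rowsum(e$w, key)
  k <- as.numeric(rownames(agg))
  list(n = e$n, i = as.integer((k - 1) %/% e$n) + 1L,
       j = as.integer((k - 1) %% e$n) + 1L, w = as.numeric(agg))
}

sum_by_node <- function(n, idx, w) {
  as.numeric(tapply(w, factor(idx, levels = seq_len(n)), sum, default = 0))
}

dist_from_ints <- function(e, weighted, both_dirs = FALSE) {
  i <- e$i; j <- e$j; w <- e$w
  if (both_dirs) {
    tmp <- i; i <- c(i, j); j <- c(j, tmp); w <- c(w, w)
  }
  len <- if (weighted) 1 / w else rep(1, length(w))
  cpp_pairwise_distances(e$n, i - 1L, j - 1L, len)
}

# component-scaled closeness of every node from a distance matrix (rows =
# sources); r reachable others at total distance d give (r/(n-1)) * (r/d)
closeness_from_dist <- function(d, scaling = "component") {
  n <- nrow(d)
  if (n < 2) return(numeric(n))
  diag(d) <- Inf
  fin <- is.finite(d)
  d[!fin] <- 0
  r <- rowSums(fin)
  dsum <- rowSums(d)
  base <- ifelse(r > 0, r / pmax(dsum, .Machine$double.xmin), 0)
  if (scaling == "component") base * r / (n - 1) else base
}

betweenness_from_ints <- function(e, weighted) {
  if (e$n < 3) return(numeric(e$n))
  len <- if (weighted) 1 / e$w else rep(1, length(e$w))
  cpp_betweenness(e$n, e$i - 1L, e$j - 1L, len) / ((e$n - 1) * (e$n - 2))
}

#' Degree centrality
#'
#' Binary degree counts distinct opponents: `in` = distinct attackers,
#' `out` = distinct victims, `total` = distinct opponents in the undirected
#' sense (a reciprocal dyad counts once). Weighted degree sums fight
#' weights: `in` = fights received, `out` = fights initiated, `total` =
#' total fight involvement (in + out; a stand-off contributes 0.5 to each).
#'
#' @param net A directed `pen_network`.
#' @param mode `"total"`, `"in"`, or `"out"`.
#' @param weighted Logical; count fights instead of opponents.
#' @param standardized Divide by `n - 1` (off by default: the unstandardized
#'   values are the ones reported; standardization changes little between
#'   similarly sized pens).
#' @return Named numeric vector over all roster animals; isolated animals
#'   get 0.
#' @export
degree_centrality <- function(net, mode = c("total", "in", "out"),
                              weighted = FALSE, standardized = FALSE) {
  mode <- match.arg(mode)
  e <- edge_ints(net)
  n <- e$n
  val <- if (weighted) {
    w_in <- sum_by_node(n, e$j, e$w)
    w_out <- sum_by_node(n, e$i, e$w)
    switch(mode, "in" = w_in, "out" = w_out, total = w_in + w_out)
  } else {
    if (mode == "total") {
      u <- undirect_ints(e)
      tabulate(c(u$i, u$j), n)
    } else {
      # aggregated edges are unique (from, to) pairs, so counting arcs
      # counts distinct partners
      tabulate(if (mode == "in") e$j else e$i, n)
    }
  }
  if (standardized) val <- val / (n - 1)
  stats::setNames(as.numeric(val), net$nodes)
}

#' Betweenness centrality
#'
#' The extent to which an animal lies on the shortest paths between other
#' pen members: for node *v*, the sum over ordered pairs (s, t) of the
#' fraction of shortest s-to-t paths passing through *v* (0 when t is
#' unreachable from s), normalized by (n-1)(n-2) so that the maximum value
#' is 1 and values are comparable across pens of different sizes. All tied
#' shortest paths are counted (Brandes path-counting accumulation, no
#' tie-breaking).
#'
#' @param net A directed `pen_network`.
#' @param weighted Logical; use edge length 1/weight instead of unit lengths.
#' @return Named numeric vector in `[0, 1]`; all zeros when n < 3.
#' @export
betweenness_centrality <- function(net, weighted = FALSE) {
  e <- edge_ints(net)
  stats::setNames(betweenness_from_ints(e, weighted), net$nodes)
}

#' Closeness centrality
#'
#' Based on inverse shortest-path distances between a focal animal and the
#' others. `out` uses paths from the focal animal (how quickly its fights
#' cascade through the pen), `in` uses paths towards it (how quickly others'
#' fights reach it), `undirected` uses the undirected projection.
#'
#' Fight networks are routinely disconnected, so closeness is
#' component-scaled by default: with `r` of the `n - 1` pen mates reachable
#' at total distance `d`,
#' \deqn{C(u) = \frac{r}{n-1} \cdot \frac{r}{d},}
#' i.e. the inverse mean distance to the reachable animals, downweighted by
#' the reachable fraction. Isolated (or pure sink/source) animals get 0, and
#' binary values stay in `[0, 1]`; weighted values may exceed 1 because
#' frequent opponents are closer than distance 1. `scaling = "off"` drops
#' the `r/(n-1)` factor and reports the plain inverse mean distance to
#' reachable animals.
#'
#' @param net A directed `pen_network`.
#' @param direction `"undirected"`, `"in"`, or `"out"`.
#' @param weighted Logical; use edge length 1/weight.
#' @param scaling `"component"` (default) or `"off"`.
#' @param projection For `direction = "undirected"` with `weighted = TRUE`:
#'   `"sum"` (default) sums the two directional weights of a dyad, `"binary"`
#'   ignores weights (union of links).
#' @return Named numeric vector; 0 for animals with no reachable pen mates.
#' @export
closeness_centrality <- function(net,
                                 direction = c("undirected", "in", "out"),
                                 weighted = FALSE,
                                 scaling = c("component", "off"),
                                 projection = c("sum", "binary")) {
  direction <- match.arg(direction)
  scaling <- match.arg(scaling)
  projection <- match.arg(projection)
  e <- edge_ints(net)
  d <- if (direction == "undirected") {
    u <- undirect_ints(e)
    if (projection == "binary") u$w <- rep(1, length(u$w))
    dist_from_ints(u, weighted, both_dirs = TRUE)
  } else {
    dist_from_ints(e, weighted)
  }
  if (direction == "in") d <- t(d)
  stats::setNames(closeness_from_dist(d, scaling), net$nodes)
}

MEASURE_COLS <- as.vector(outer(
  c("degree", "in_degree", "out_degree", "betweenness",
    "closeness", "in_closeness", "out_closeness"),
  c("binary", "weighted"), paste, sep = "_"
))

#' Names of the centrality measure columns
#'
#' The 14 measure variants reported by [centrality_table()]: degree,
#' in-degree, out-degree, betweenness, closeness, ingoing closeness and
#' outgoing closeness, each as `_binary` and `_weighted`.
#'
#' @return Character vector of column names.
#' @export
centrality_measures <- function() MEASURE_COLS

pen_centrality_rows <- function(net, standardized, scaling) {
  e <- edge_ints(net)
  n <- e$n
  u <- undirect_ints(e)
  deg_std <- if (standardized) n - 1 else 1

  d_dir_b <- dist_from_ints(e, FALSE)
  d_dir_w <- dist_from_ints(e, TRUE)
  d_und_b <- dist_from_ints(u, FALSE, both_dirs = TRUE)
  d_und_w <- dist_from_ints(u, TRUE, both_dirs = TRUE)

  tibble::tibble(
    animal_id = net$nodes,
    pen_id = net$pen_id,
    age_level = net$age_level,
    n_pen = n,
    degree_binary = tabulate(c(u$i, u$j), n) / deg_std,
    degree_weighted = (sum_by_node(n, e$i, e$w) + sum_by_node(n, e$j, e$w)) / deg_std,
    in_degree_binary = tabulate(e$j, n) / deg_std,
    in_degree_weighted = sum_by_node(n, e$j, e$w) / deg_std,
    out_degree_binary = tabulate(e$i, n) / deg_std,
    out_degree_weighted = sum_by_node(n, e$i, e$w) / deg_std,
    betweenness_binary = betweenness_from_ints(e, FALSE),
    betweenness_weighted = betweenness_from_ints(e, TRUE),
    closeness_binary = closeness_from_dist(d_und_b, scaling),
    closeness_weighted = closeness_from_dist(d_und_w, scaling),
    in_closeness_binary = closeness_from_dist(t(d_dir_b), scaling),
    in_closeness_weighted = closeness_from_dist(t(d_dir_w), scaling),
    out_closeness_binary = closeness_from_dist(d_dir_b, scaling),
    out_closeness_weighted = closeness_from_dist(d_dir_w, scaling)
  )
}

#' Per-animal centrality table
#'
#' Computes all 14 measure variants (7 measures x binary/weighted) for every
#' roster animal of every pen: degree, in-degree, out-degree, betweenness,
#' and undirected/ingoing/outgoing closeness.
#'
#' @param nets List of directed `pen_network` objects (see
#'   [build_networks()]).
#' @param standardized Standardize degree by `n - 1` (default `FALSE`).
#' @param scaling Closeness scaling, see [closeness_centrality()].
#' @return A tibble with one row per (animal, pen), columns `animal_id`,
#'   `pen_id`, `age_level`, `n_pen` and one column per measure variant
#'   (`degree_binary`, `degree_weighted`, ..., `out_closeness_weighted`),
#'   ordered by (age level in rearing order, pen, animal).
#' @export
centrality_table <- function(nets, standardized = FALSE, scaling = "component") {
  if (inherits(nets, "pen_network")) nets <- list(nets)
  rows <- lapply(nets, pen_centrality_rows,
                 standardized = standardized, scaling = scaling)
  out <- dplyr::bind_rows(rows)
  ord <- order(match(out$age_level, age_levels()), out$pen_id, out$animal_id)
  out[ord, ]
}
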