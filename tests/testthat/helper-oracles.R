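# Independent oracles: brute-force shortest-path enumeration for the
# centrality kernels, and a first-principles tie-corrected H statistic with
# full enumeration of group assignments for the rank tests. These never call
# the implementation they check.

ORACLE_TIE_EPS <- 1e-10

# All simple paths between every ordered pair by depth-first enumeration;
# returns shortest-path distances, path counts (sigma), and per-node
# through-counts on shortest paths.
oracle_shortest_paths <- function(n, from, to, len) {
  stopifnot(n <= 8)
  nbr <- lapply(seq_len(n), function(u) which(from == u))
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  through <- array(0, dim = c(n, n, n))
  for (s in seq_len(n)) {
    # collect (target, length, interior nodes) of every simple path from s
    paths_len <- vector("list", n)
    paths_int <- vector("list", n)
    dfs <- function(v, visited, d, interior) {
      for (k in nbr[[v]]) {
        t <- to[k]
        if (visited[t]) next
        dt <- d + len[k]
        paths_len[[t]][[length(paths_len[[t]]) + 1]] <<- dt
        paths_int[[t]][[length(paths_int[[t]]) + 1]] <<- interior
        visited[t] <- TRUE
        dfs(t, visited, dt, c(interior, t))
        visited[t] <- FALSE
      }
    }
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    dfs(s, visited, 0, integer())
    for (t in seq_len(n)) {
      if (t == s || !length(paths_len[[t]])) next
      lens <- unlist(paths_len[[t]])
      d <- min(lens)
      dist[s, t] <- d
      shortest <- which(lens <= d + ORACLE_TIE_EPS)
      sigma[s, t] <- length(shortest)
      for (p in shortest) {
        interior <- setdiff(paths_int[[t]][[p]], t)
        through[s, t, interior] <- through[s, t, interior] + 1
      }
    }
  }
  list(dist = dist, sigma = sigma, through = through)
}

oracle_betweenness <- function(n, from, to, len) {
  if (n < 3) return(numeric(n))
  sp <- oracle_shortest_paths(n, from, to, len)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || sp$sigma[s, t] == 0) next
    bc <- bc + sp$through[s, t, ] / sp$sigma[s, t]
  }
  bc / ((n - 1) * (n - 2))
}

oracle_closeness <- function(dist_row, n, scaling = "component") {
  reach <- is.finite(dist_row)
  r <- sum(reach)
  if (r == 0) return(0)
  base <- r / sum(dist_row[reach])
  if (scaling == "component") base * r / (n - 1) else base
}

# random directed pen network with half-integer weights, possibly
# disconnected; uses the current RNG state
random_pen_network <- function(n, p = 0.4) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, ]
  events <- fight_events(
    pen_id = rep("rp", nrow(e)), age_level = rep("weaned", nrow(e)),
    animal_a = e$from, animal_b = e$to,
    start_time = rep(43200, nrow(e)),
    duration_s = rep(2, nrow(e)), standoff = rep(FALSE, nrow(e))
  )
  net <- build_network(events, tibble::tibble(
    pen_id = "rp", age_level = "weaned", animal_id = nodes))
  # replace unit weights by random half-integers in [0.5, 5]
  net$edges$weight <- sample(seq(0.5, 5, by = 0.5), nrow(net$edges), replace = TRUE)
  net
}

# integer arrays of a pen_network's directed edges for the oracles
net_arrays <- function(net) {
  list(n = length(net$nodes),
       from = match(net$edges$from, net$nodes),
       to = match(net$edges$to, net$nodes),
       w = net$edges$weight)
}

# ---- rank-statistic oracles -------------------------------------------------

# tie-corrected Kruskal-Wallis H from first principles
oracle_kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n_i <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, rep(seq_along(groups), n_i), mean)
  h <- 12 / (N * (N + 1)) * sum(n_i * rbar^2) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) return(0)
  h / corr
}

# every distinct assignment of the pooled values to groups of the given
# sizes (exact permutation null for N <= 8)
enumerate_assignments <- function(values, sizes) {
  N <- length(values)
  stopifnot(sum(sizes) == N, N <= 8)
  out <- list()
  recurse <- function(remaining_idx, k, acc) {
    if (k > length(sizes)) {
      out[[length(out) + 1]] <<- lapply(acc, function(ix) values[ix])
      return()
    }
    if (length(remaining_idx) == sizes[k]) {
      recurse(integer(), k + 1, c(acc, list(remaining_idx)))
      return()
    }
    cmb <- utils::combn(remaining_idx, sizes[k])
    for (c in seq_len(ncol(cmb))) {
      recurse(setdiff(remaining_idx, cmb[, c]), k + 1, c(acc, list(cmb[, c])))
    }
  }
  recurse(seq_len(N), 1, list())
  out
}
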