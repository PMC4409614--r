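# Directed weighted aggregated fight networks, one per pen.
#
# Each clear fight contributes weight 1 to the directed edge
# initiator -> receiver; each stand-off contributes 0.5 to each of the two
# opposite directed edges, so the total edge weight of a network always
# equals the number of contributing events. All weights are multiples of 0.5
# and therefore exact in double precision, which keeps the conservation
# checks exact rather than approximate.

# sum parallel contributions into one weight per ordered node pair, sorted
# by (from, to)
aggregate_edges <- function(from, to, w) {
  if (!length(from)) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = numeric()))
  }
  key <- paste(from, to, sep = "\r")
  agg <- rowsum(w, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  tibble::tibble(
    from = vapply(parts, `[[`, character(1), 1),
    to = vapply(parts, `[[`, character(1), 2),
    weight = as.numeric(agg)
  )
}

new_pen_network <- function(pen_id, age_level, nodes, edges, directed = TRUE) {
  structure(
    list(pen_id = pen_id, age_level = age_level,
         nodes = nodes, edges = edges, directed = directed),
    class = "pen_network"
  )
}

#' Build the aggregated agonistic network of one pen
#'
#' Nodes are the full pen roster (animals with no fights become isolated
#' nodes); directed links run from the initiator to the receiver of each
#' fight and are weighted by contact frequency between the two opponents.
#' A stand-off fight, whose initiator could not be identified, is split into
#' two opposite directed links of half weight each.
#'
#' @param events Fight-event tibble, all from one pen.
#' @param roster Roster tibble restricted to that pen (one `pen_id`, one
#'   `age_level`).
#' @return A `pen_network` object: fields `pen_id`, `age_level`, `nodes`
#'   (character vector), `edges` (tibble `from`, `to`, `weight`), `directed`.
#' @export
build_network <- function(events, roster) {
  pen <- unique(roster$pen_id)
  lvl <- unique(roster$age_level)
  if (length(pen) != 1 || length(lvl) != 1) {
    abort("roster must describe exactly one (pen_id, age_level)",
          class = "agonet_validation_error")
  }
  nodes <- sort(unique(roster$animal_id))
  if (nrow(events)) {
    if (!all(events$pen_id == pen) || !all(events$age_level == lvl)) {
      abort("events do not all belong to the roster's pen and age level",
            class = "agonet_validation_error")
    }
    stray <- setdiff(unique(c(events$animal_a, events$animal_b)), nodes)
    if (length(stray)) {
      abort(paste0("event participant(s) not on the pen roster: ",
                   paste(stray, collapse = ", ")),
            class = "agonet_validation_error")
    }
  }
  so <- events$standoff
  from <- c(events$animal_a[!so], events$animal_a[so], events$animal_b[so])
  to <- c(events$animal_b[!so], events$animal_b[so], events$animal_a[so])
  w <- c(rep(1, sum(!so)), rep(0.5, 2 * sum(so)))
  edges <- aggregate_edges(from, to, w)
  new_pen_network(pen, lvl, nodes, edges, directed = TRUE)
}

#' Build networks for every pen of a study
#'
#' @param events Fight-event tibble (any number of pens).
#' @param roster Full roster tibble.
#' @return Named list of `pen_network` objects, ordered by (age level in
#'   rearing order, pen id); names are `"<age_level>/<pen_id>"`.
#' @export
build_networks <- function(events, roster) {
  key <- dplyr::distinct(roster, .data$age_level, .data$pen_id) |>
    dplyr::mutate(ord = match(.data$age_level, age_levels())) |>
    dplyr::arrange(.data$ord, .data$pen_id)
  kk <- paste(key$age_level, key$pen_id, sep = "\r")
  ev_key <- paste(events$age_level, events$pen_id, sep = "\r")
  if (!all(ev_key %in% kk)) {
    stray <- events$pen_id[!ev_key %in% kk][1]
    abort(paste0("events reference pen ", stray, " absent from the roster"),
          class = "agonet_validation_error")
  }
  ev_grp <- split(seq_len(nrow(events)),
                  factor(paste(events$age_level, events$pen_id, sep = "\r"),
                         levels = kk))
  ro_grp <- split(seq_len(nrow(roster)),
                  factor(paste(roster$age_level, roster$pen_id, sep = "\r"),
                         levels = kk))
  nets <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    nets[[i]] <- build_network(events[ev_grp[[i]], ], roster[ro_grp[[i]], ])
  }
  names(nets) <- paste(key$age_level, key$pen_id, sep = "/")
  nets
}

#' @export
print.pen_network <- function(x, ...) {
  cat(sprintf("<pen_network> pen %s (%s), %d animals, %d %s edges, total weight %.1f\n",
              x$pen_id, x$age_level, length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected", total_weight(x)))
  invisible(x)
}

#' Total edge weight of a network
#'
#' For a directed fight network this equals the number of contributing
#' events (stand-offs contribute 2 x 0.5); the undirected projection
#' preserves it.
#'
#' @param net A `pen_network`.
#' @return Numeric scalar.
#' @export
total_weight <- function(net) sum(net$edges$weight)

#' Binarize a network
#'
#' Every positive-weight link becomes weight 1 ("present"); the node set is
#' unchanged. Idempotent.
#'
#' @param net A `pen_network`.
#' @return A `pen_network` with unit weights.
#' @export
binarize <- function(net) {
  edges <- net$edges[net$edges$weight > 0, ]
  edges$weight <- rep(1, nrow(edges))
  new_pen_network(net$pen_id, net$age_level, net$nodes, edges, net$directed)
}

#' Undirected projection of a directed network
#'
#' Animals that fought each other are linked regardless of who initiated;
#' the undirected weight of a dyad is the sum of the two directional
#' weights, so the total contact frequency between the opponents (and the
#' network's total weight) is preserved.
#'
#' @param net A directed `pen_network`.
#' @return An undirected `pen_network`; edges stored once per dyad with
#'   `from < to`.
#' @export
undirected_projection <- function(net) {
  if (!net$directed) return(net)
  e <- net$edges
  edges <- aggregate_edges(pmin(e$from, e$to), pmax(e$from, e$to), e$weight)
  new_pen_network(net$pen_id, net$age_level, net$nodes, edges, directed = FALSE)
}

#' Convert a pen network to an igraph graph
#'
#' @param net A `pen_network`.
#' @return An igraph object with edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(net$edges[c("from", "to")]),
    directed = net$directed,
    vertices = data.frame(name = net$nodes)
  )
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' Write a network as an edge-list CSV
#'
#' Columns `source,target,weight`. Isolated nodes do not appear in the edge
#' list; pair the file with the roster to recover them.
#'
#' @param net A `pen_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  out <- net$edges
  names(out) <- c("source", "target", "weight")
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Full node set (including isolates) with a `weight` edge attribute,
#' readable by standard graph tools.
#'
#' @param net A `pen_network`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
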