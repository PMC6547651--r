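#' Select habitat patches on aquatic cells
#'
#' Samples `floor(habitat_fraction * #aquatic)` distinct aquatic cells
#' uniformly without replacement and assigns each a random habitat
#' quality `~ Uniform(0.5, 1)` and carrying capacity
#' `K = quality * K_max`. Qualities bounded away from zero avoid
#' degenerate patches whose fill times diverge.
#'
#' @param raster a `cost_raster` with at least one aquatic cell.
#' @param config a [scenario_config()].
#' @param seed integer seed (defaults to the `patches` substream of the
#'   configuration seed).
#' @return a data frame of patches: `id`, `row`, `col`, `quality`, `K`.
#' @export
select_patches <- function(raster, config = scenario_config(),
                           seed = substream_seed(config$seed, "patches")) {
  aq <- which(raster$aquatic)
  if (length(aq) == 0) stop("raster has no aquatic cells")
  n <- floor(config$habitat_fraction * length(aq))
  if (n < 1)
    stop("habitat_fraction ", config$habitat_fraction, " selects no patch ",
         "from ", length(aq), " aquatic cells")
  set.seed(seed)
  cells <- sort(sample(aq, n))
  quality <- runif(n, 0.5, 1)
  data.frame(id = seq_len(n),
             row = (cells - 1L) %% raster$rows + 1L,
             col = (cells - 1L) %/% raster$rows + 1L,
             quality = quality,
             K = quality * config$K_max)
}

#' Least-cost distance between two raster cells
#'
#' Accumulated traversal cost of the cheapest 8-connected path under the
#' standard GIS cost-distance convention: a move costs the arithmetic
#' mean of the two cell costs, times `sqrt(2)` for diagonal moves. On a
#' straight 4-neighbour run of `n` steps through uniform cost `c` this
#' equals `n * c`, so 25 agricultural cells at cost 50 cost exactly
#' 1250. The measure is symmetric in its endpoints.
#'
#' @param raster a `cost_raster`.
#' @param a,b cells as `(row, col)`.
#' @param return_path also return the cells of one optimal path.
#' @return the cost, or (with `return_path`) a list with `cost` and
#'   `path` (a matrix of rows/cols from `a` to `b`).
#' @export
least_cost_distance <- function(raster, a, b, return_path = FALSE) {
  res <- .grid_dijkstra_cpp(raster$cost, a[1], a[2], Inf)
  d <- res$dist[b[1], b[2]]
  if (!return_path) return(d)
  # backtrack predecessors from b to a
  nr <- raster$rows
  path <- integer(0)
  cur <- (b[2] - 1L) * nr + b[1]
  start <- (a[2] - 1L) * nr + a[1]
  repeat {
    path <- c(cur, path)
    if (cur == start) break
    cur <- res$pred[cur]
  }
  list(cost = d,
       path = cbind(row = (path - 1L) %% nr + 1L,
                    col = (path - 1L) %/% nr + 1L))
}

#' Build the habitat network G = (V, E)
#'
#' Connects every pair of patches whose least-cost distance across the
#' cost raster is strictly below the dispersal budget `C_max`; the edge
#' carries that distance as its cost `C(e)`. Strictness keeps the
#' survival factor `1 - C(e)/C_max` positive on every edge. The network
#' may be disconnected. One truncated Dijkstra sweep is run per patch
#' (accumulated cost capped at `C_max`), so only sub-budget distances
#' are ever computed.
#'
#' @param patches data frame from [select_patches()].
#' @param raster the `cost_raster` the patches live on.
#' @param config a [scenario_config()].
#' @return a `habitat_network`: list with `patches`, `edges`
#'   (`from`, `to`, `cost`; `from < to`), `C_max` and an igraph
#'   representation `graph` (vertex names are patch ids).
#' @export
build_network <- function(patches, raster, config = scenario_config()) {
  stopifnot(nrow(patches) >= 1)
  nr <- raster$rows
  cells <- (patches$col - 1L) * nr + patches$row
  from <- integer(0); to <- integer(0); cost <- numeric(0)
  for (i in seq_len(nrow(patches))) {
    res <- .grid_dijkstra_cpp(raster$cost, patches$row[i], patches$col[i],
                              config$C_max)
    j <- which(patches$id > patches$id[i])
    d <- res$dist[cells[j]]
    keep <- is.finite(d) & d < config$C_max
    from <- c(from, rep(patches$id[i], sum(keep)))
    to <- c(to, patches$id[j][keep])
    cost <- c(cost, d[keep])
  }
  edges <- data.frame(from = from, to = to, cost = cost)
  stopifnot(all(edges$cost > 0), all(edges$cost < config$C_max))
  new_habitat_network(patches, edges, config$C_max)
}

new_habitat_network <- function(patches, edges, C_max) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) transform(edges, from = as.character(from),
                                   to = as.character(to))
        else data.frame(from = character(0), to = character(0),
                        cost = numeric(0)),
    directed = FALSE,
    vertices = data.frame(name = as.character(patches$id),
                          quality = patches$quality, K = patches$K))
  structure(list(patches = patches, edges = edges, C_max = C_max,
                 graph = g),
            class = "habitat_network")
}

#' @export
print.habitat_network <- function(x, ...) {
  cat(sprintf("<habitat_network> %d patches, %d edges (C_max = %g)\n",
              nrow(x$patches), nrow(x$edges), x$C_max))
  if (nrow(x$edges))
    cat(sprintf("  edge costs: %.1f - %.1f\n",
                min(x$edges$cost), max(x$edges$cost)))
  invisible(x)
}

patch_index <- function(network, ids) {
  idx <- match(ids, network$patches$id)
  if (anyNA(idx)) stop("unknown patch id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Restrict a habitat network to a patch subset
#'
#' Induced subnetwork on the given patch ids; ids are preserved.
#' @param network a `habitat_network`.
#' @param ids patch ids to keep.
#' @return a `habitat_network`.
#' @export
induce_subnetwork <- function(network, ids) {
  patch_index(network, ids)
  keep <- network$patches$id %in% ids
  e <- network$edges
  e <- e[e$from %in% ids & e$to %in% ids, , drop = FALSE]
  new_habitat_network(network$patches[keep, , drop = FALSE], e,
                      network$C_max)
}

#' Write / read a habitat network
#'
#' GraphML via igraph (node attributes `name` = id, `quality`, `K`;
#' edge attribute `cost`), or a pair of CSV files (`<prefix>_nodes.csv`,
#' `<prefix>_edges.csv`).
#'
#' @param network a `habitat_network`.
#' @param path GraphML file path.
#' @return `read_network()` returns a `habitat_network`.
#' @export
write_network <- function(network, path) {
  g <- network$graph
  igraph::V(g)$row <- network$patches$row
  igraph::V(g)$col <- network$patches$col
  igraph::V(g)$C_max <- network$C_max
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  patches <- data.frame(id = as.integer(igraph::V(g)$name),
                        row = as.integer(igraph::V(g)$row),
                        col = as.integer(igraph::V(g)$col),
                        quality = igraph::V(g)$quality,
                        K = igraph::V(g)$K)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
                      cost = if (igraph::ecount(g)) igraph::E(g)$cost
                             else numeric(0))
  sw <- edges$from > edges$to
  tmp <- edges$from[sw]; edges$from[sw] <- edges$to[sw]; edges$to[sw] <- tmp
  new_habitat_network(patches, edges[order(edges$from, edges$to), ,
                                     drop = FALSE],
                      igraph::V(g)$C_max[1])
}

#' @rdname write_network
#' @param prefix path prefix for the CSV pair.
#' @export
write_network_csv <- function(network, prefix) {
  write.csv(network$patches, paste0(prefix, "_nodes.csv"),
            row.names = FALSE)
  write.csv(network$edges, paste0(prefix, "_edges.csv"), row.names = FALSE)
  invisible(prefix)
}

# Cost-weighted shortest-path distances between patches on the habitat
# graph (not the raster): used for time horizons and source-distance
# covariates.
network_distances <- function(network, from_ids, to_ids) {
  g <- network$graph
  igraph::distances(g, v = as.character(from_ids),
                    to = as.character(to_ids),
                    weights = igraph::E(g)$cost)
}

network_shortest_path <- function(network, from_id, to_id) {
  g <- network$graph
  sp <- igraph::shortest_paths(g, from = as.character(from_id),
                               to = as.character(to_id),
                               weights = igraph::E(g)$cost,
                               output = "vpath")
  as.integer(names(sp$vpath[[1]]))
}
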