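#' Serial fill time along a path
#'
#' Time to colonise the habitat patches of a path one after another,
#' each from its predecessor alone, under the colonisation rules of the
#' optimisation model: the sum over the path's edges of
#' `ceil(T_SH / (K(v_i) * S_DIS * (1 - C(v_i, v_{i+1})/C_max)))`,
#' where `v_i` is the emitting (tail) patch of each edge. Along a
#' cost-shortest path from the nearest source this is the `TH1` upper
#' bound on the minimum colonisation time; a single-patch path has fill
#' time 0.
#'
#' @param path vector of patch ids; consecutive patches must be network
#'   neighbours.
#' @param network a `habitat_network`.
#' @param config a [scenario_config()].
#' @return integer number of time steps.
#' @export
path_fill_time <- function(path, network, config = scenario_config()) {
  if (length(path) <= 1) return(0L)
  idx <- patch_index(network, path)
  e <- network$edges
  total <- 0L
  for (k in seq_len(length(path) - 1)) {
    a <- path[k]; b <- path[k + 1]
    hit <- which((e$from == a & e$to == b) | (e$from == b & e$to == a))
    if (length(hit) == 0)
      stop("patches ", a, " and ", b, " are not network neighbours")
    surv <- 1 - e$cost[hit[1]] / network$C_max
    K_tail <- network$patches$K[idx[k]]
    total <- total + ceiling(config$T_SH / (K_tail * config$S_DIS * surv))
  }
  as.integer(total)
}

# Upper bound on the minimum colonisation time from a feasible
# sequential schedule: colonise exactly one patch at a time, with every
# already-colonised neighbour jointly feeding it at full capacity
# (nothing else is being colonised, so no emission budget is shared).
# The next patch is chosen greedily by fill time plus hop distance to
# the destination, so the schedule heads for the destination but can
# still exploit joint colonisation; on a single-source path network it
# reduces exactly to the serial fill time TH1.
cooperative_fill_bound <- function(network, sources, dest, config) {
  n <- nrow(network$patches)
  src_idx <- patch_index(network, sources)
  dest_idx <- patch_index(network, dest)
  e <- network$edges
  ti <- c(patch_index(network, e$from), patch_index(network, e$to))
  hi <- c(patch_index(network, e$to), patch_index(network, e$from))
  rate <- rep(config$S_DIS * (1 - e$cost / network$C_max), 2) *
    network$patches$K[ti]
  adj_in <- split(data.frame(u = ti, rate = rate), hi)
  hd <- apply(igraph::distances(network$graph,
                                v = as.character(dest), weights = NA),
              2, min)
  colonised <- logical(n)
  colonised[src_idx] <- TRUE
  if (colonised[dest_idx]) return(0L)
  sum_rate <- numeric(n)
  for (v in as.integer(names(adj_in))) {
    a <- adj_in[[as.character(v)]]
    sum_rate[v] <- sum(a$rate[colonised[a$u]])
  }
  t_cur <- 0
  repeat {
    cand <- which(!colonised & sum_rate > 0 & is.finite(hd))
    if (length(cand) == 0) return(NA_integer_) # unreachable
    dt <- ceiling(config$T_SH / sum_rate[cand])
    v <- cand[which.min(dt + hd[cand])]
    t_cur <- t_cur + ceiling(config$T_SH / sum_rate[v])
    if (v == dest_idx) return(as.integer(t_cur))
    colonised[v] <- TRUE
    a <- adj_in[[as.character(v)]]
    # v now feeds its uncolonised neighbours
    for (k in seq_len(nrow(a))) {
      u <- a$u[k]
      if (!colonised[u]) {
        b <- adj_in[[as.character(u)]]
        sum_rate[u] <- sum_rate[u] + b$rate[b$u == v][1]
      }
    }
  }
}

#' Choose the MIP time horizon
#'
#' Computes cost-weighted shortest paths from every initial source
#' habitat to the destination; `TH1` is the serial fill time
#' ([path_fill_time()]) along the nearest source's path and `TH2` the
#' same for the second-nearest connected source (when one exists; the
#' integer rounding can make `TH2 < TH1`). A third upper bound,
#' `TH_coop`, comes from a sequential cooperative schedule in which
#' every already-colonised neighbour jointly feeds the next patch —
#' much tighter than the serial bounds in dense neighbourhoods where
#' joint colonisation dominates. All three are feasible colonisation
#' schedules, hence upper bounds on the optimum; the horizon is their
#' minimum, capped at `horizon_block` (default 30), with escalation to
#' higher multiples handled by [minimum_colonisation_time()].
#'
#' @param network a `habitat_network`.
#' @param sources initial source habitat ids.
#' @param dest a single destination patch id.
#' @param config a [scenario_config()].
#' @return a `time_horizon` list: `T` =
#'   `min(TH1, TH2, TH_coop, horizon_block)`, `TH1`, `TH2` (`NA` when
#'   only one source is connected), `TH_coop`, `reachable`,
#'   and the `nearest`/`second` source ids. `T = 0` when the destination
#'   is itself a source; `reachable = FALSE` (with `T = NA`) when no
#'   source connects to the destination, in which case the MIP would be
#'   infeasible for every horizon.
#' @export
choose_time_horizon <- function(network, sources, dest,
                                config = scenario_config()) {
  stopifnot(length(dest) == 1)
  patch_index(network, c(sources, dest))
  out <- list(T = NA_integer_, TH1 = NA_integer_, TH2 = NA_integer_,
              TH_coop = NA_integer_, reachable = FALSE,
              nearest = NA_integer_, second = NA_integer_)
  class(out) <- "time_horizon"
  if (dest %in% sources) {
    out$T <- 0L; out$TH1 <- 0L; out$TH_coop <- 0L; out$reachable <- TRUE
    out$nearest <- dest
    return(out)
  }
  d <- network_distances(network, sources, dest)[, 1]
  conn <- which(is.finite(d))
  if (length(conn) == 0) return(out)
  ord <- conn[order(d[conn])]
  out$reachable <- TRUE
  out$nearest <- sources[ord[1]]
  p1 <- network_shortest_path(network, out$nearest, dest)
  out$TH1 <- path_fill_time(p1, network, config)
  if (length(ord) >= 2) {
    out$second <- sources[ord[2]]
    p2 <- network_shortest_path(network, out$second, dest)
    out$TH2 <- path_fill_time(p2, network, config)
  }
  out$TH_coop <- cooperative_fill_bound(network, sources, dest, config)
  out$T <- min(out$TH1, out$TH2, out$TH_coop, config$horizon_block,
               na.rm = TRUE)
  out
}

# Instance reduction: a patch can only matter for colonising the
# destinations within T steps if its hop distance from some source plus
# its hop distance to some destination is at most T (holdover arcs cost
# no hops; every move arc advances one layer). Preserves the optimum.
prune_patches <- function(network, sources, dests, T) {
  g <- network$graph  # vertex order matches the patches table
  hs <- igraph::distances(g, v = as.character(sources), weights = NA)
  hs <- apply(hs, 2, min)
  hd <- igraph::distances(g, v = as.character(dests), weights = NA)
  keep <- rep(FALSE, nrow(network$patches))
  for (k in seq_along(dests)) keep <- keep | (hs + hd[k, ] <= T)
  union(network$patches$id[keep], dests)
}

#' Minimum colonisation time of destination habitats
#'
#' The full optimisation pipeline: chooses the time horizon per
#' destination ([choose_time_horizon()]; for several destinations the
#' maximum of the per-destination horizons), builds the time-expanded
#' network and the MIP, solves it, and on infeasibility escalates the
#' horizon cap by multiples of `horizon_block`
#' (`min(TH1, TH2, 30)`, then `min(TH1, TH2, 60)`, ...) until feasible
#' — `TH1` is itself a feasible schedule, so the escalation terminates
#' at `min(TH1, TH2)` at the latest, and infeasibility there signals an
#' internal inconsistency. The result is a provable lower bound: no
#' dispersal behaviour respecting the emission cap and the
#' cost-proportional mortality can colonise the destinations earlier.
#'
#' @param network a `habitat_network`.
#' @param sources initial source habitat ids.
#' @param H_dest destination patch ids.
#' @param config a [scenario_config()].
#' @param prune drop patches that cannot influence the optimum (hop
#'   distance from sources plus hop distance to a destination exceeds
#'   the horizon) before expanding in time; the optimum is unchanged.
#' @param compute_route also decompose the optimal flows into a
#'   colonisation route ([extract_route()]).
#' @param time_limit per-solve time limit in seconds.
#' @return a `colonisation_time` list: `t_star`, `T_used`, `horizons`
#'   (per destination), `route` (when requested), `solution` (the
#'   audited `mip_solution`) and `ten`. When some destination is
#'   unreachable from every source, `t_star` is `NA` and `status` is
#'   `"unreachable"`.
#' @export
minimum_colonisation_time <- function(network, sources, H_dest,
                                      config = scenario_config(),
                                      prune = TRUE, compute_route = TRUE,
                                      time_limit = config$time_limit) {
  stopifnot(length(sources) >= 1, length(H_dest) >= 1)
  hz <- lapply(H_dest, function(d)
    choose_time_horizon(network, sources, d, config))
  names(hz) <- H_dest
  if (!all(vapply(hz, `[[`, TRUE, "reachable")))
    return(structure(list(status = "unreachable", t_star = NA_integer_,
                          horizons = hz),
                     class = "colonisation_time"))
  TH_d <- vapply(hz,
                 function(h) min(h$TH1, h$TH2, h$TH_coop, na.rm = TRUE),
                 0)
  if (max(TH_d) == 0) { # every destination is already a source
    return(structure(list(status = "optimal", t_star = 0L, T_used = 0L,
                          horizons = hz, route = NULL, solution = NULL),
                     class = "colonisation_time"))
  }
  block <- config$horizon_block
  mult <- 1L
  repeat {
    T <- max(pmin(TH_d, block * mult))
    T <- max(T, 1L)
    net <- network
    srcs <- sources
    if (prune) {
      keep <- prune_patches(network, sources, H_dest, T)
      net <- induce_subnetwork(network, keep)
      srcs <- intersect(sources, keep)
    }
    # valid layer windows from hop distances: a patch cannot be a
    # source before hs(v) (biomass advances one edge per layer) and
    # cannot contribute after T - hd(v) (its emissions could no longer
    # reach a destination copy within the horizon)
    hs <- apply(igraph::distances(net$graph, v = as.character(srcs),
                                  weights = NA), 2, min)
    hd <- apply(igraph::distances(net$graph, v = as.character(H_dest),
                                  weights = NA), 2, min)
    earliest <- as.integer(pmin(hs, T + 1))
    latest <- T - hd
    latest[!is.finite(latest)] <- 0
    ten <- build_ten(net, srcs, T, config, latest = as.integer(latest))
    inst <- build_mip(ten, H_dest, config, earliest = earliest)
    sol <- solve_mip(inst, solver = config$solver,
                     time_limit = time_limit)
    if (sol$status == "timeout")
      return(structure(list(status = "timeout", t_star = NA_integer_,
                            T_used = T, horizons = hz),
                       class = "colonisation_time"))
    if (sol$status == "optimal") {
      route <- if (compute_route) extract_route(sol, ten, H_dest)
               else NULL
      return(structure(list(status = "optimal",
                            t_star = sol$t_star, T_used = T,
                            horizons = hz, route = route,
                            solution = sol, ten = ten),
                       class = "colonisation_time"))
    }
    if (T >= max(TH_d))
      stop("MIP infeasible at T = min(TH1, TH2) = ", T,
           "; TH1 is a feasible schedule, so this indicates an ",
           "internal inconsistency")
    mult <- mult + 1L
  }
}

#' @export
print.colonisation_time <- function(x, ...) {
  if (x$status != "optimal") {
    cat("<colonisation_time>", x$status, "\n")
  } else {
    cat(sprintf("<colonisation_time> t* = %d (horizon %d)\n",
                x$t_star, x$T_used))
  }
  invisible(x)
}

#' Decompose optimal flows into a colonisation route
#'
#' Standard path decomposition of the positive-flow subnetwork from the
#' super source to the destination copies at the optimal layer: paths
#' are extracted by repeatedly backtracking along the
#' largest-remaining-flow incoming arc (deterministic), each path
#' carrying its bottleneck amount, until at least `T_SH` biomass is
#' accounted for at every destination copy. Time stamps strictly
#' increase along each path (the time-expanded network is layered, so
#' residual positive-flow cycles cannot arise; the `residual` field
#' reports leftover untraceable flow instead of raising).
#'
#' @param solution an optimal [solve_mip()] solution.
#' @param ten the [build_ten()] network it was solved on.
#' @param dests destination patch ids to trace to (default: every patch
#'   colonised at the optimal layer).
#' @return a `colonisation_route`: list of paths, each with `patches`
#'   (ids, `NA` for the super source), `times` and `amount`, plus a
#'   `residual` diagnostic.
#' @export
extract_route <- function(solution, ten, dests = NULL) {
  stopifnot(solution$status == "optimal")
  arcs <- ten$arcs
  fr <- solution$flows
  ids <- ten$network$patches$id
  t_star <- solution$t_star
  if (is.null(dests)) # default: every patch colonised at the hit layer
    dests <- which(solution$x_copies[, t_star + 1] == 1)
  else dests <- patch_index(ten$network, dests)
  in_of <- split(seq_len(nrow(arcs)), arcs$head)
  paths <- list()
  residual <- 0
  tol <- 1e-7
  for (dv in dests) {
    target <- ten_copy(ten, dv, t_star)
    traced <- 0
    repeat {
      if (traced >= ten$T_SH - tol) break
      # backtrack greedily along the largest remaining incoming flow
      path_arcs <- integer(0)
      cur <- target
      ok <- TRUE
      repeat {
        cin <- in_of[[as.character(cur)]]
        cin <- cin[fr[cin] > tol]
        if (length(cin) == 0) { ok <- FALSE; break }
        a <- cin[which.max(fr[cin])]
        path_arcs <- c(a, path_arcs)
        if (arcs$type[a] == "source") break
        cur <- arcs$tail[a]
      }
      if (!ok) break
      amt <- min(fr[path_arcs])
      fr[path_arcs] <- fr[path_arcs] - amt
      traced <- traced + amt
      nodes_v <- arcs$head_v[path_arcs]
      nodes_t <- ifelse(is.na(arcs$t_from[path_arcs]), 0L,
                        arcs$t_from[path_arcs] + 1L)
      keep <- !duplicated(nodes_v)  # collapse holdover repeats
      paths[[length(paths) + 1]] <-
        list(patches = ids[nodes_v[keep]],
             times = nodes_t[keep],
             dest = ids[dv],
             amount = amt)
    }
    if (traced < ten$T_SH - tol)
      residual <- residual + (ten$T_SH - traced)
  }
  structure(list(paths = paths, residual = residual, t_star = t_star),
            class = "colonisation_route")
}

#' @export
print.colonisation_route <- function(x, ...) {
  cat(sprintf("<colonisation_route> %d path(s), arrival layer %d\n",
              length(x$paths), x$t_star))
  for (p in x$paths) {
    cat(sprintf("  %.3g units: %s\n", p$amount,
                paste(sprintf("%s@t%d", p$patches, p$times),
                      collapse = " -> ")))
  }
  if (x$residual > 1e-7)
    cat(sprintf("  residual untraced demand: %.3g\n", x$residual))
  invisible(x)
}
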