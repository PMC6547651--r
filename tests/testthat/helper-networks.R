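# Hand-built fixtures used across test files.

# A path network 1 - 2 - ... - k with given edge costs and capacities.
chain_network <- function(costs, K = rep(100, length(costs) + 1),
                          C_max = 1250) {
  k <- length(costs) + 1
  patches <- data.frame(id = seq_len(k), row = 1L,
                        col = as.integer(seq(1, 10 * k, length.out = k)),
                        quality = K / max(K), K = K)
  colonet:::new_habitat_network(
    patches, data.frame(from = seq_len(k - 1), to = 2:k, cost = costs),
    C_max)
}

# Arbitrary network from an edge list.
toy_network <- function(edges, K, C_max = 1250) {
  n <- length(K)
  patches <- data.frame(id = seq_len(n), row = 1L, col = seq_len(n),
                        quality = K / max(K), K = K)
  colonet:::new_habitat_network(patches, edges, C_max)
}

# Random connected-ish instance for property tests: n patches, edge
# probability p, costs uniform in (0.2, 0.95) * C_max.
random_instance <- function(n, seed, p = 0.35, C_max = 1250,
                            K_max = 100) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  # ensure a spanning path so everything is reachable
  spine <- cbind(1:(n - 1), 2:n)
  el <- unique(rbind(pairs[keep, , drop = FALSE], spine))
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      cost = runif(nrow(el), 0.2, 0.95) * C_max)
  K <- runif(n, 0.5, 1) * K_max
  toy_network(edges, K, C_max)
}

# Independent oracle for the minimum colonisation time on a chain with
# a single source at patch 1 and destination at the far end: enumerate
# all integer inter-colonisation schedules d_i (time between patch i
# and patch i+1 becoming sources) up to a cap and keep the fastest one
# in which every patch accumulates T_SH from its predecessor alone
# (arrival rate K(v_i) * S_DIS * (1 - C/C_max) per step).
chain_min_time_enum <- function(net, config) {
  k <- nrow(net$patches)
  if (k == 1) return(0L)
  e <- net$edges
  rate <- net$patches$K[seq_len(k - 1)] * config$S_DIS *
    (1 - e$cost / net$C_max)
  cap <- ceiling(config$T_SH / rate) + 1 # enumerate up to fill time + 1
  grids <- lapply(cap, function(m) seq_len(m))
  combos <- expand.grid(grids)
  feasible <- apply(combos, 1, function(d) all(d * rate >= config$T_SH))
  min(rowSums(combos)[feasible])
}

# Brute-force least-cost distance by enumerating every simple path on a
# small grid (8-connectivity, mean-of-cells step costs).
brute_force_lcd <- function(cost, a, b) {
  nr <- nrow(cost); nc <- ncol(cost)
  target <- (b[2] - 1) * nr + b[1]
  best <- Inf
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  recurse <- function(cell, acc, visited) {
    if (acc >= best) return()
    if (cell == target) { best <<- acc; return() }
    r <- (cell - 1) %% nr + 1; c <- (cell - 1) %/% nr + 1
    for (m in seq_len(nrow(moves))) {
      r2 <- r + moves$dr[m]; c2 <- c + moves$dc[m]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      nxt <- (c2 - 1) * nr + r2
      if (visited[nxt]) next
      step <- 0.5 * (cost[cell] + cost[nxt]) *
        ifelse(moves$dr[m] != 0 & moves$dc[m] != 0, sqrt(2), 1)
      visited[nxt] <- TRUE
      recurse(nxt, acc + step, visited)
      visited[nxt] <- FALSE
    }
  }
  visited <- logical(nr * nc)
  start <- (a[2] - 1) * nr + a[1]
  visited[start] <- TRUE
  recurse(start, 0, visited)
  best
}

# Uniform all-agriculture raster.
uniform_raster <- function(rows, cols, config = scenario_config()) {
  build_cost_raster(matrix(1L, rows, cols), NULL, config)
}
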