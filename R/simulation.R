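#' Initialise a simulation state
#'
#' Initial sources start fully colonised at their carrying capacity; all
#' other patches hold no biomass.
#'
#' @param network a `habitat_network`.
#' @param sources patch ids initially colonised (may be empty).
#' @return a `simulation_state`: list with `t` (= 0), `biomass` and
#'   `is_source` (both named by patch id).
#' @export
init_state <- function(network, sources) {
  ids <- network$patches$id
  if (length(sources)) patch_index(network, sources)
  biomass <- setNames(numeric(length(ids)), ids)
  is_source <- setNames(logical(length(ids)), ids)
  src <- ids %in% sources
  biomass[src] <- network$patches$K[src]
  is_source[src] <- TRUE
  structure(list(t = 0L, biomass = biomass, is_source = is_source),
            class = "simulation_state")
}

# Directed-edge arrays for the per-step update: for each directed edge
# (tail -> head), `deliver` is the fraction of the tail's emigrant pool
# that arrives at the head: share (normalised allocation weight) times
# the survival factor 1 - C/C_max.
sim_precompute <- function(network, config) {
  e <- network$edges
  tails <- c(e$from, e$to)
  heads <- c(e$to, e$from)
  surv <- rep(1 - e$cost / network$C_max, 2)
  w <- switch(config$allocation,
              survival = surv,
              inverse_cost = rep(1 / e$cost, 2))
  ti <- patch_index(network, tails)
  hi <- patch_index(network, heads)
  W <- rowsum(w, ti)            # allocation normaliser per tail patch
  Wv <- numeric(nrow(network$patches))
  Wv[as.integer(rownames(W))] <- W
  list(ti = ti, hi = hi, deliver = (w / Wv[ti]) * surv,
       K = network$patches$K, n = nrow(network$patches))
}

#' Advance the simulation by one time step
#'
#' Every source habitat `v` emits an emigrant pool `S_DIS * K(v)`
#' (or `S_DIS * B(v)` under logistic growth), split among *all* its
#' neighbours with shares proportional to the allocation weight
#' (default: the survival factor `1 - C/C_max`, so cheap connections
#' receive a bigger share); the amount arriving is the share reduced by
#' the cost-proportional mortality `C/C_max`. Arrivals at patches that
#' are already sources are discarded; other patches accumulate them.
#' Any patch whose accumulated biomass reaches `T_SH` at the end of the
#' step is a source habitat from the next step on (instant growth resets
#' its biomass to the carrying capacity). Updates are synchronous: a
#' patch crossing the threshold does not emit in the same step.
#'
#' @param state a `simulation_state`.
#' @param network a `habitat_network`.
#' @param config a [scenario_config()].
#' @return the `simulation_state` at `t + 1`.
#' @export
sim_step <- function(state, network, config = scenario_config()) {
  pre <- sim_precompute(network, config)
  sim_step_fast(state, pre, config)
}

sim_step_fast <- function(state, pre, config) {
  src <- state$is_source
  biomass <- state$biomass
  pool <- config$S_DIS * if (config$growth == "instant") pre$K else biomass
  act <- src[pre$ti] & !src[pre$hi]       # arrivals at sources are discarded
  if (any(act)) {
    contrib <- pool[pre$ti[act]] * pre$deliver[act]
    arr <- rowsum(contrib, pre$hi[act])
    biomass[as.integer(rownames(arr))] <-
      biomass[as.integer(rownames(arr))] + arr
  }
  if (config$growth == "logistic") {
    g <- src & biomass < pre$K
    biomass[g] <- pmin(pre$K[g],
                       biomass[g] + config$growth_rate * biomass[g] *
                         (1 - biomass[g] / pre$K[g]))
  }
  newly <- !src & biomass >= config$T_SH
  if (config$growth == "instant") biomass[newly] <- pre$K[newly]
  state$biomass <- biomass
  state$is_source <- src | newly
  state$t <- state$t + 1L
  state
}

#' Run the dispersal simulation
#'
#' Iterates [sim_step()] for up to `config$sim_max_steps` steps (the
#' loop ends early once every patch is colonised, after which the state
#' is constant) and records, per patch, the first time step at which it
#' became a source habitat. The simulation is deterministic: identical
#' inputs give identical results.
#'
#' @param network a `habitat_network`.
#' @param sources patch ids initially colonised.
#' @param config a [scenario_config()].
#' @param record_trajectory also keep the per-step biomass table.
#' @return a `simulation_result`: `first_colonised` (named by patch id;
#'   `NA` when never colonised within the cap), `steps_run`, the final
#'   `state`, and optionally `trajectory` (steps x patches matrix).
#' @export
run_simulation <- function(network, sources, config = scenario_config(),
                           record_trajectory = FALSE) {
  state <- init_state(network, sources)
  pre <- sim_precompute(network, config)
  ids <- network$patches$id
  first <- setNames(rep(NA_integer_, length(ids)), ids)
  first[state$is_source] <- 0L
  traj <- if (record_trajectory)
    matrix(state$biomass, 1, length(ids),
           dimnames = list(NULL, ids)) else NULL
  steps <- 0L
  while (steps < config$sim_max_steps && !all(state$is_source)) {
    was <- state$is_source
    state <- sim_step_fast(state, pre, config)
    steps <- steps + 1L
    newly <- state$is_source & !was
    first[newly] <- steps
    if (record_trajectory) traj <- rbind(traj, state$biomass)
  }
  structure(list(first_colonised = first, steps_run = steps,
                 state = state, trajectory = traj),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- length(x$first_colonised)
  done <- sum(!is.na(x$first_colonised))
  cat(sprintf("<simulation_result> %d/%d patches colonised in %d steps\n",
              done, n, x$steps_run))
  invisible(x)
}

#' Write simulation results as CSV
#'
#' One row per patch (`patch_id`, `first_colonised_step`; empty when
#' never colonised), plus an optional long-format trajectory file.
#'
#' @param result a `simulation_result`.
#' @param path output CSV path.
#' @param trajectory_path optional CSV path for the trajectory.
#' @export
write_simulation_csv <- function(result, path, trajectory_path = NULL) {
  write.csv(data.frame(patch_id = as.integer(names(result$first_colonised)),
                       first_colonised_step = result$first_colonised),
            path, row.names = FALSE)
  if (!is.null(trajectory_path) && !is.null(result$trajectory)) {
    tr <- result$trajectory
    long <- data.frame(step = rep(seq_len(nrow(tr)) - 1L, ncol(tr)),
                       patch_id = rep(as.integer(colnames(tr)),
                                      each = nrow(tr)),
                       biomass = as.vector(tr))
    write.csv(long, trajectory_path, row.names = FALSE)
  }
  invisible(path)
}
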