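#' Paired simulation/optimisation experiment
#'
#' Reproduces the comparison design: on one habitat network, draw
#' `n_source_sets` random sets of initial source habitats (each
#' `floor(source_fraction * |V|)` patches) and `n_destinations` random
#' destination patches; run the dispersal simulation once per source
#' set (dispersal is undirected and deterministic, so one run yields
#' the colonisation time of every patch) and the optimisation model
#' once per (source set, destination) pair.
#'
#' A destination that is in the source set short-circuits to
#' `t_opt = t_sim = 0`; a destination unreachable from every source in
#' the habitat graph is recorded with status `"unreachable"` (never
#' dropped silently); a destination not colonised within
#' `sim_max_steps` has `t_sim = NA` (censored).
#'
#' @param network a `habitat_network`.
#' @param config a [scenario_config()].
#' @param n_source_sets,n_destinations design size (the full-scale
#'   design is 50 x 50).
#' @param seed master seed for the `sources` / `destinations`
#'   substreams (defaults to the configuration seed).
#' @param time_limit per-optimisation solver budget in seconds; a pair
#'   whose solve exceeds it is recorded with status `"timeout"`
#'   (`t_opt = NA`) rather than blocking the experiment.
#' @param verbose print one progress line per source set.
#' @return an `experiment_records` data frame, one row per pair:
#'   `source_set_id`, `destination_id`, `t_opt`, `t_sim`,
#'   `nearest_cost` (least network cost from any connected source to
#'   the destination), `mean_cost` (mean over all connected sources),
#'   `status`.
#' @export
run_experiment <- function(network, config = scenario_config(),
                           n_source_sets = 50, n_destinations = 50,
                           seed = config$seed, time_limit = 120,
                           verbose = interactive()) {
  ids <- network$patches$id
  if (length(ids) < n_destinations)
    stop("network has fewer patches than requested destinations")
  n_src <- max(1L, floor(config$source_fraction * length(ids)))
  set.seed(substream_seed(seed, "sources"))
  source_sets <- lapply(seq_len(n_source_sets),
                        function(i) sort(sample(ids, n_src)))
  set.seed(substream_seed(seed, "destinations"))
  dests <- sort(sample(ids, n_destinations))
  rows <- vector("list", n_source_sets * n_destinations)
  k <- 0L
  for (s in seq_len(n_source_sets)) {
    srcs <- source_sets[[s]]
    sim <- run_simulation(network, srcs, config)
    d_all <- network_distances(network, srcs, dests)
    for (j in seq_len(n_destinations)) {
      dest <- dests[j]
      dvec <- d_all[, j]
      conn <- is.finite(dvec)
      nearest <- if (any(conn)) min(dvec[conn]) else NA_real_
      meanc <- if (any(conn)) mean(dvec[conn]) else NA_real_
      if (dest %in% srcs) {
        t_opt <- 0L; status <- "optimal"
      } else if (!any(conn)) {
        t_opt <- NA_integer_; status <- "unreachable"
      } else {
        res <- minimum_colonisation_time(network, srcs, dest, config,
                                         compute_route = FALSE,
                                         time_limit = time_limit)
        t_opt <- res$t_star
        status <- res$status
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        source_set_id = s, destination_id = dest,
        t_opt = t_opt,
        t_sim = as.integer(sim$first_colonised[as.character(dest)]),
        nearest_cost = nearest, mean_cost = meanc,
        status = status)
    }
    if (verbose)
      message(sprintf("source set %d/%d done", s, n_source_sets))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_records", class(out))
  out
}

#' Comparison statistics between optimisation and simulation
#'
#' Summarises a table of paired runs: the Pearson correlation between
#' the optimisation minimum time and the dispersal cost from the
#' nearest connected source (and from the mean over all connected
#' sources), and the speed factor — the mean over runs of the per-run
#' ratio `t_sim / t_opt` for pairs with a colonised destination and
#' `t_opt >= 1` (the ratio is undefined at `t_opt = 0`; such runs are
#' counted and excluded). Censored runs (`t_sim` unknown after the
#' simulation cap) are excluded from the speed factor and summarised by
#' their `t_opt` distribution.
#'
#' @param records an `experiment_records` data frame.
#' @return a `model_comparison` list: `n_records`, `r_nearest`,
#'   `r_mean`, `speed_factor` (`mean`, `median`, `range`, `n`),
#'   `censored` (`n`, `t_opt_mean`, `t_opt_median`, `t_opt_range`),
#'   `n_zero_opt`, `n_unreachable`.
#' @export
compare_models <- function(records) {
  ok_opt <- !is.na(records$t_opt)
  usable <- ok_opt & !is.na(records$nearest_cost)
  if (sum(usable) == 0)
    return(structure(list(n_records = nrow(records), r_nearest = NA_real_,
                          r_mean = NA_real_,
                          speed_factor = list(mean = NA_real_,
                                              median = NA_real_,
                                              range = c(NA_real_, NA_real_),
                                              n = 0L),
                          censored = list(n = 0L),
                          n_zero_opt = 0L,
                          n_unreachable = sum(records$status == "unreachable")),
                     class = "model_comparison"))
  r_nearest <- cor(records$t_opt[usable], records$nearest_cost[usable])
  r_mean <- cor(records$t_opt[usable], records$mean_cost[usable])
  both <- ok_opt & !is.na(records$t_sim)
  ratio_ok <- both & records$t_opt >= 1
  ratios <- records$t_sim[ratio_ok] / records$t_opt[ratio_ok]
  cens <- ok_opt & is.na(records$t_sim) & records$status != "unreachable"
  structure(list(
    n_records = nrow(records),
    r_nearest = r_nearest,
    r_mean = r_mean,
    speed_factor = list(
      mean = if (length(ratios)) mean(ratios) else NA_real_,
      median = if (length(ratios)) median(ratios) else NA_real_,
      range = if (length(ratios)) range(ratios) else c(NA_real_, NA_real_),
      n = length(ratios)),
    censored = list(
      n = sum(cens),
      t_opt_mean = if (any(cens)) mean(records$t_opt[cens]) else NA_real_,
      t_opt_median = if (any(cens)) median(records$t_opt[cens]) else NA_real_,
      t_opt_range = if (any(cens)) range(records$t_opt[cens])
                    else c(NA_real_, NA_real_)),
    n_zero_opt = sum(both & records$t_opt == 0),
    n_unreachable = sum(records$status == "unreachable")),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>", x$n_records, "paired runs\n")
  cat(sprintf("  r(t_opt, nearest-source cost) = %.3f\n", x$r_nearest))
  cat(sprintf("  r(t_opt, mean-source cost)    = %.3f\n", x$r_mean))
  cat(sprintf("  speed factor t_sim/t_opt: mean %.2f, median %.2f, range %.1f-%.1f (n = %d)\n",
              x$speed_factor$mean, x$speed_factor$median,
              x$speed_factor$range[1], x$speed_factor$range[2],
              x$speed_factor$n))
  cat(sprintf("  censored simulations: %d; t_opt = 0 pairs excluded from ratios: %d; unreachable: %d\n",
              x$censored$n, x$n_zero_opt, x$n_unreachable))
  invisible(x)
}

#' Write experiment outputs
#'
#' Records as CSV (one row per pair) and the comparison summary as
#' JSON.
#'
#' @param records an `experiment_records` data frame.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_experiment <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
  cmp <- compare_models(records)
  jsonlite::write_json(unclass(cmp), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
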