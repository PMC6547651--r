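#' Scenario configuration
#'
#' Bundles every tunable parameter of the landscape generator, the habitat
#' network construction, the dispersal simulation and the optimisation
#' model, so that a whole analysis is reproducible from `(config, seed)`.
#'
#' The defaults describe a generic aquatic invertebrate with a terrestrial
#' life stage dispersing over a 100 m raster: a maximum overland dispersal
#' distance of 2500 m through open agricultural land, per-cell dispersal
#' costs of 50 (agriculture), 75 (forest), 100 (urban) and 25 (aquatic)
#' cost units, and a derived dispersal budget
#' `C_max = agriculture_cost * max_dispersal_m / cell_size_m` (1250 with
#' the defaults). Two habitat patches are connected when the least-cost
#' path between them costs strictly less than `C_max`.
#'
#' @param cell_size_m raster cell edge length in metres.
#' @param max_dispersal_m maximum dispersal distance through open
#'   agricultural land, in metres; must be a multiple of `cell_size_m`.
#' @param agriculture_cost,forest_cost,urban_cost,aquatic_cost per-cell
#'   dispersal costs of the four land-cover classes (cost units).
#' @param T_SH colonisation threshold: the minimum viable population in
#'   biomass units; a patch holding at least `T_SH` counts as fully
#'   occupied and becomes a source habitat.
#' @param S_DIS fraction of its carrying capacity a source habitat can
#'   emit per time step (its dispersal capacity is `S_DIS * K(v)`);
#'   must lie strictly between 0 and 1.
#' @param K_max carrying capacity of a perfect-quality patch (biomass
#'   units); a patch's capacity is `quality * K_max`.
#' @param habitat_fraction fraction of aquatic cells selected as habitat
#'   patches, in (0, 1].
#' @param source_fraction fraction of patches initially colonised, in
#'   (0, 1].
#' @param sim_max_steps simulation cap in time steps.
#' @param horizon_block escalation block of the optimiser's time horizon
#'   (the horizon is `min(TH1, TH2, horizon_block)`, escalated by
#'   multiples of `horizon_block` on infeasibility).
#' @param seed integer master seed; per-stage substreams are derived from
#'   it, see [substream_seed()].
#' @param proportions named fractions of the terrestrial land-cover
#'   classes (`agriculture`, `forest`, `urban`); must sum to 1. The
#'   default is the 66.6/11.1/22.2 mix normalised to sum exactly to 1.
#' @param cluster_p occupation probability of the percolation step of the
#'   random-cluster land-cover generator (see [generate_landcover()]).
#' @param aquatic_fraction target fraction of cells occupied by the
#'   synthetic stream network.
#' @param allocation how a source habitat splits its emigrants among
#'   neighbours: `"survival"` weights by `1 - C(e)/C_max` (the survival
#'   factor, shared with the optimisation model) or `"inverse_cost"`
#'   weights by `1/C(e)`.
#' @param growth population growth after the threshold is crossed:
#'   `"instant"` jumps straight to the carrying capacity (mirrors the
#'   optimisation model's simplification); `"logistic"` ramps up at rate
#'   `growth_rate`.
#' @param growth_rate intrinsic logistic growth rate per time step (only
#'   used when `growth = "logistic"`).
#' @param solver MILP backend name; currently `"highs"` (via Python
#'   scipy).
#' @param time_limit solver time limit in seconds (`Inf` for none).
#'
#' @return An object of class `scenario_config`: a validated list with
#'   the derived budget `C_max` filled in.
#' @seealso [load_config()], [derive_cmax()]
#' @examples
#' cfg <- scenario_config()
#' cfg$C_max # 1250 with the defaults
#' @export
scenario_config <- function(cell_size_m = 100,
                            max_dispersal_m = 2500,
                            agriculture_cost = 50,
                            forest_cost = 75,
                            urban_cost = 100,
                            aquatic_cost = 25,
                            T_SH = 10,
                            S_DIS = 0.1,
                            K_max = 100,
                            habitat_fraction = 0.10,
                            source_fraction = 0.10,
                            sim_max_steps = 250L,
                            horizon_block = 30L,
                            seed = 1L,
                            proportions = c(agriculture = 2 / 3,
                                            forest = 1 / 9,
                                            urban = 2 / 9),
                            cluster_p = 0.5,
                            aquatic_fraction = 19490 / 250000,
                            allocation = c("survival", "inverse_cost"),
                            growth = c("instant", "logistic"),
                            growth_rate = 1.0,
                            solver = "highs",
                            time_limit = Inf) {
  cfg <- list(
    cell_size_m = as.numeric(cell_size_m),
    max_dispersal_m = as.numeric(max_dispersal_m),
    agriculture_cost = as.numeric(agriculture_cost),
    forest_cost = as.numeric(forest_cost),
    urban_cost = as.numeric(urban_cost),
    aquatic_cost = as.numeric(aquatic_cost),
    T_SH = as.numeric(T_SH),
    S_DIS = as.numeric(S_DIS),
    K_max = as.numeric(K_max),
    habitat_fraction = as.numeric(habitat_fraction),
    source_fraction = as.numeric(source_fraction),
    sim_max_steps = as.integer(sim_max_steps),
    horizon_block = as.integer(horizon_block),
    seed = as.integer(seed),
    proportions = proportions,
    cluster_p = as.numeric(cluster_p),
    aquatic_fraction = as.numeric(aquatic_fraction),
    allocation = match.arg(allocation),
    growth = match.arg(growth),
    growth_rate = as.numeric(growth_rate),
    solver = as.character(solver),
    time_limit = as.numeric(time_limit)
  )
  class(cfg) <- "scenario_config"
  cfg$C_max <- derive_cmax(cfg)
  validate_config(cfg)
}

#' Derive the dispersal budget C_max
#'
#' The budget is the cost of walking `max_dispersal_m / cell_size_m`
#' raster cells of open agricultural land:
#' `C_max = agriculture_cost * (max_dispersal_m / cell_size_m)`
#' (1250 cost units with the defaults: 50 cost units times 25 cells).
#'
#' @param config a [scenario_config()].
#' @return the budget in cost units.
#' @examples
#' derive_cmax(scenario_config()) # 1250
#' @export
derive_cmax <- function(config) {
  ncell <- config$max_dispersal_m / config$cell_size_m
  if (abs(ncell - round(ncell)) > 1e-9) {
    stop("max_dispersal_m (", config$max_dispersal_m,
         ") is not a multiple of cell_size_m (", config$cell_size_m, ")")
  }
  config$agriculture_cost * round(ncell)
}

validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid configuration field '", field, "': ", why, call. = FALSE)
  }
  num1 <- function(field, positive = TRUE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x))
      fail(field, "must be a single number")
    if (positive && x <= 0) fail(field, "must be > 0")
    x
  }
  for (f in c("cell_size_m", "max_dispersal_m", "agriculture_cost",
              "forest_cost", "urban_cost", "aquatic_cost", "T_SH",
              "K_max", "growth_rate")) num1(f)
  num1("time_limit")
  if (cfg$S_DIS <= 0 || cfg$S_DIS >= 1)
    fail("S_DIS", "must lie strictly between 0 and 1")
  for (f in c("habitat_fraction", "source_fraction", "aquatic_fraction")) {
    x <- num1(f)
    if (x > 1) fail(f, "must lie in (0, 1]")
  }
  if (cfg$cluster_p <= 0 || cfg$cluster_p >= 1)
    fail("cluster_p", "must lie strictly between 0 and 1")
  if (!is.numeric(cfg$sim_max_steps) || cfg$sim_max_steps < 1)
    fail("sim_max_steps", "must be a positive integer")
  if (!is.numeric(cfg$horizon_block) || cfg$horizon_block < 1)
    fail("horizon_block", "must be a positive integer")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    fail("seed", "must be a single integer")
  pr <- cfg$proportions
  need <- c("agriculture", "forest", "urban")
  if (is.null(names(pr)) || !all(need %in% names(pr)))
    fail("proportions", "must be named fractions for agriculture, forest, urban")
  pr <- pr[need]
  if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
    fail("proportions", "must be non-negative and sum to 1")
  cfg$proportions <- pr
  if (!identical(cfg$allocation %in% c("survival", "inverse_cost"), TRUE))
    fail("allocation", "must be 'survival' or 'inverse_cost'")
  if (!identical(cfg$growth %in% c("instant", "logistic"), TRUE))
    fail("growth", "must be 'instant' or 'logistic'")
  cmax <- derive_cmax(cfg)
  if (!isTRUE(all.equal(cfg$C_max, cmax)))
    fail("C_max", "is derived; do not set it directly")
  cfg
}

#' Read a scenario configuration from JSON
#'
#' Unknown fields are rejected; missing fields take the documented
#' defaults of [scenario_config()]. `C_max` is always re-derived, never
#' read.
#'
#' @param path path to a JSON file (an empty object `{}` yields the
#'   default configuration).
#' @return a validated [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) raw <- list()
  if (!is.list(raw)) stop("configuration must be a JSON object")
  allowed <- setdiff(names(formals(scenario_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$proportions)) raw$proportions <- unlist(raw$proportions)
  do.call(scenario_config, raw)
}

#' Derive a per-stage random substream seed
#'
#' The master seed fans out into named substreams (landscape, streams,
#' patches, qualities, sources, destinations, ...) so that each stage can
#' be regenerated independently and deterministically.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stage) {
  # small string hash, stable across platforms/sessions
  h <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) + 31))
  as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483646)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  raster: %g m cells, dispersal budget C_max = %g (%g m max)\n",
              x$cell_size_m, x$C_max, x$max_dispersal_m))
  cat(sprintf("  costs: agriculture %g, forest %g, urban %g, aquatic %g\n",
              x$agriculture_cost, x$forest_cost, x$urban_cost, x$aquatic_cost))
  cat(sprintf("  demography: T_SH = %g, S_DIS = %g, K_max = %g, growth = %s\n",
              x$T_SH, x$S_DIS, x$K_max, x$growth))
  cat(sprintf("  fractions: habitat %g, source %g, aquatic %g\n",
              x$habitat_fraction, x$source_fraction, x$aquatic_fraction))
  cat(sprintf("  sim cap %d steps; horizon block %d; seed %d\n",
              x$sim_max_steps, x$horizon_block, x$seed))
  invisible(x)
}
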