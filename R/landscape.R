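#' Land-cover class codes
#'
#' Integer codes used in land-cover grids: agriculture = 1, forest = 2,
#' urban = 3, aquatic = 4.
#' @export
LANDCOVER_CLASSES <- c(agriculture = 1L, forest = 2L, urban = 3L,
                       aquatic = 4L)

class_costs <- function(config) {
  c(config$agriculture_cost, config$forest_cost, config$urban_cost,
    config$aquatic_cost)
}

#' Generate a spatially autocorrelated land-cover grid
#'
#' A modified random-cluster neutral landscape model: cells are occupied
#' independently with probability `cluster_p`, the 4-connected clusters
#' of occupied cells are each assigned a terrestrial land-cover class
#' with probability equal to the target class proportion, and the
#' remaining cells inherit the majority class among their already
#' assigned 8-neighbours (iterated until the grid is full). The result
#' is a clustered (not i.i.d.) classification whose empirical class
#' fractions converge to the requested proportions as the grid grows.
#'
#' @param rows,cols grid dimensions.
#' @param proportions named fractions over `agriculture`, `forest`,
#'   `urban`; must sum to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @param cluster_p percolation occupation probability; the default 0.5
#'   is subcritical for 4-connectivity (threshold 0.593), keeping
#'   clusters finite so class fractions concentrate.
#' @return an integer matrix of class codes in `{1, 2, 3}` (see
#'   [LANDCOVER_CLASSES]).
#' @export
generate_landcover <- function(rows, cols,
                               proportions = c(agriculture = 2 / 3,
                                               forest = 1 / 9,
                                               urban = 2 / 9),
                               seed = 1L, cluster_p = 0.5) {
  need <- c("agriculture", "forest", "urban")
  if (is.null(names(proportions)) || !all(need %in% names(proportions)))
    stop("proportions must be named over agriculture, forest, urban")
  pr <- proportions[need]
  if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
    stop("proportions must be non-negative and sum to 1")
  set.seed(seed)
  mask <- matrix(runif(rows * cols) < cluster_p, rows, cols)
  lab <- .cc_label_cpp(mask, 4L)
  ncl <- max(lab)
  grid <- matrix(0L, rows, cols)
  if (ncl > 0) {
    cls <- sample.int(3L, ncl, replace = TRUE, prob = pr)
    grid[mask] <- cls[lab[mask]]
  }
  fill_majority(grid, pr)
}

# Assign every 0 cell the majority class among its assigned 8-neighbours,
# iterating outward; random tie-breaks. Cells with no assigned neighbour
# anywhere (e.g. a fully empty percolation map) are drawn i.i.d.
fill_majority <- function(grid, pr) {
  nr <- nrow(grid); nc <- ncol(grid)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  while (any(grid == 0L)) {
    counts <- lapply(1:3, function(k) {
      ind <- (grid == k) * 1
      Reduce(`+`, Map(function(dr, dc) shift(ind, dr, dc),
                      offs$dr, offs$dc))
    })
    tot <- counts[[1]] + counts[[2]] + counts[[3]]
    todo <- grid == 0L & tot > 0
    if (!any(todo)) { # isolated remainder: draw i.i.d.
      nz <- sum(grid == 0L)
      grid[grid == 0L] <- sample.int(3L, nz, replace = TRUE, prob = pr)
      break
    }
    noise <- lapply(1:3, function(k)
      counts[[k]][todo] + runif(sum(todo)) * 0.5)
    pick <- max.col(do.call(cbind, noise))
    grid[todo] <- as.integer(pick)
  }
  grid
}

#' Generate a synthetic dendritic stream network
#'
#' Drainage-network surrogate built by headward channel growth. A main
#' channel is carved from a boundary outlet by a direction-persistent
#' random walk; tributaries are then grown by space-filling extension:
#' a target cell is drawn uniformly at random over the grid and a
#' channel is extended from the nearest stream cell toward it (with
#' directional jitter) until it reaches the target or is blocked, so
#' empty regions attract growth and the network spreads over the whole
#' landscape instead of thickening around the outlet. Every added cell
#' must touch exactly one existing stream cell (4-connectivity), so the
#' stream set is a tree on the grid at every step — connected, acyclic
#' and branching, emulating a dendritic drainage system at low density.
#' Growth stops when the target number of stream cells is reached
#' (exactly).
#'
#' @param rows,cols grid dimensions.
#' @param outlet `(row, col)` of the outlet; must lie on the grid
#'   boundary.
#' @param fraction target fraction of grid cells turned aquatic (the
#'   default reproduces a density of 19,490 aquatic cells per 500 x 500
#'   grid); ignored when `target_cells` is given.
#' @param target_cells absolute number of stream cells (overrides
#'   `fraction`).
#' @param seed integer seed.
#' @return a logical `rows x cols` matrix marking stream (aquatic)
#'   cells.
#' @export
generate_stream_network <- function(rows, cols,
                                    outlet = c(rows, ceiling(cols / 2)),
                                    fraction = 19490 / 250000,
                                    target_cells = NULL,
                                    seed = 1L) {
  n <- rows * cols
  if (is.null(target_cells)) target_cells <- max(1L, round(fraction * n))
  target_cells <- as.integer(target_cells)
  if (target_cells < 1 || target_cells > n)
    stop("target stream size ", target_cells,
         " infeasible for a ", rows, "x", cols, " grid")
  r0 <- outlet[1]; c0 <- outlet[2]
  if (r0 < 1 || r0 > rows || c0 < 1 || c0 > cols ||
      !(r0 %in% c(1, rows) || c0 %in% c(1, cols)))
    stop("outlet must lie on the grid boundary")
  set.seed(seed)
  root <- (c0 - 1L) * rows + r0
  if (n == 1) return(matrix(TRUE, 1, 1))
  in_stream <- logical(n)
  nb_count <- integer(n) # stream 4-neighbours per cell
  stream_cells <- integer(target_cells)
  count <- 0L
  # directions: 1 = -row (up), 2 = +row (down), 3 = -col, 4 = +col
  step_of <- c(-1L, 1L, -rows, rows)
  cell_rc <- function(i) c((i - 1L) %% rows + 1L, (i - 1L) %/% rows + 1L)
  on_grid_move <- function(i, d) {
    r <- (i - 1L) %% rows + 1L; c <- (i - 1L) %/% rows + 1L
    switch(d, r > 1L, r < rows, c > 1L, c < cols)
  }
  add_cell <- function(i) {
    in_stream[i] <<- TRUE
    count <<- count + 1L
    stream_cells[count] <<- i
    rc <- cell_rc(i)
    for (d in 1:4) if (on_grid_move(i, d))
      nb_count[i + step_of[d]] <<- nb_count[i + step_of[d]] + 1L
  }
  # a cell may join the stream only if it touches exactly one stream cell
  admissible <- function(i) !in_stream[i] && nb_count[i] == 1L
  turn <- list(c(3L, 4L), c(3L, 4L), c(1L, 2L), c(1L, 2L))
  walk <- function(from, dir) {
    cur <- from
    repeat {
      if (count >= target_cells) return(invisible())
      # persistent direction: mostly straight, sometimes a lateral turn
      dirs <- if (runif(1) < 0.85) c(dir, sample(turn[[dir]]))
              else c(sample(turn[[dir]]), dir)
      moved <- FALSE
      for (d in dirs) {
        if (!on_grid_move(cur, d)) next
        nxt <- cur + step_of[d]
        if (admissible(nxt)) {
          add_cell(nxt)
          cur <- nxt; dir <- d; moved <- TRUE
          break
        }
      }
      if (!moved) return(invisible())
    }
  }
  # extend a channel from `from` toward the cell `tgt`, preferring the
  # axis with the larger remaining offset, with directional jitter
  walk_toward <- function(from, tgt) {
    cur <- from
    tr <- (tgt - 1L) %% rows + 1L; tc <- (tgt - 1L) %/% rows + 1L
    repeat {
      if (count >= target_cells || cur == tgt) return(invisible())
      r <- (cur - 1L) %% rows + 1L; c <- (cur - 1L) %/% rows + 1L
      dirs <- integer(0)
      if (tr < r) dirs <- c(dirs, 1L) else if (tr > r) dirs <- c(dirs, 2L)
      if (tc < c) dirs <- c(dirs, 3L) else if (tc > c) dirs <- c(dirs, 4L)
      if (length(dirs) == 2L) {
        major <- if (abs(tr - r) >= abs(tc - c)) 1L else 2L
        if (runif(1) < 0.3) major <- 3L - major
        dirs <- dirs[c(major, 3L - major)]
      }
      moved <- FALSE
      for (d in dirs) {
        nxt <- cur + step_of[d]
        if (admissible(nxt)) {
          add_cell(nxt)
          cur <- nxt; moved <- TRUE
          break
        }
      }
      if (!moved) return(invisible())
    }
  }
  add_cell(root)
  # main channel heads away from the outlet's boundary edge
  dir0 <- if (r0 == rows) 1L else if (r0 == 1) 2L
          else if (c0 == cols) 3L else 4L
  walk(root, dir0)
  fails <- 0L
  while (count < target_cells) {
    tgt <- sample.int(n, 1L)
    if (in_stream[tgt]) next
    sc <- stream_cells[seq_len(count)]
    d2 <- ((sc - 1L) %% rows - (tgt - 1L) %% rows)^2 +
      ((sc - 1L) %/% rows - (tgt - 1L) %/% rows)^2
    origin <- sc[which.min(d2)]
    before <- count
    walk_toward(origin, tgt)
    if (count == before) {
      fails <- fails + 1L
      if (fails > 10000L)
        stop("stream growth stalled at ", count,
             " cells; lower the target")
    } else fails <- 0L
  }
  matrix(in_stream, rows, cols)
}

#' Build a cost raster from land cover and streams
#'
#' Stream cells are reclassified as aquatic regardless of the underlying
#' land-cover class; every cell then carries the dispersal cost of its
#' class.
#'
#' @param landcover integer class matrix from [generate_landcover()].
#' @param streams logical matrix from [generate_stream_network()], or
#'   `NULL` for none.
#' @param config a [scenario_config()] supplying the four class costs.
#' @return a `cost_raster`: a list with `rows`, `cols`, `landcover`
#'   (integer codes incl. aquatic = 4), `cost` (numeric matrix) and
#'   `aquatic` (logical mask).
#' @export
build_cost_raster <- function(landcover, streams = NULL, config = scenario_config()) {
  lc <- landcover
  if (!is.null(streams)) {
    stopifnot(identical(dim(lc), dim(streams)))
    lc[streams] <- LANDCOVER_CLASSES[["aquatic"]]
  }
  if (!all(lc %in% 1:4)) stop("landcover contains unknown class codes")
  cost <- matrix(class_costs(config)[lc], nrow(lc), ncol(lc))
  structure(list(rows = nrow(lc), cols = ncol(lc), landcover = lc,
                 cost = cost, aquatic = lc == 4L),
            class = "cost_raster")
}

#' Generate a full landscape from a configuration
#'
#' Convenience wrapper chaining [generate_landcover()],
#' [generate_stream_network()] and [build_cost_raster()], using the
#' `landscape` and `streams` substreams of the configuration seed.
#'
#' @param config a [scenario_config()].
#' @param rows,cols grid dimensions.
#' @return a `cost_raster`.
#' @export
generate_landscape <- function(config, rows, cols) {
  lc <- generate_landcover(rows, cols, config$proportions,
                           seed = substream_seed(config$seed, "landscape"),
                           cluster_p = config$cluster_p)
  st <- generate_stream_network(rows, cols,
                                fraction = config$aquatic_fraction,
                                seed = substream_seed(config$seed, "streams"))
  build_cost_raster(lc, st, config)
}

#' @export
print.cost_raster <- function(x, ...) {
  fr <- table(factor(x$landcover, levels = 1:4,
                     labels = names(LANDCOVER_CLASSES))) / length(x$landcover)
  cat(sprintf("<cost_raster> %d x %d cells\n", x$rows, x$cols))
  cat("  class fractions:",
      paste(sprintf("%s %.3f", names(fr), as.numeric(fr)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a grid as Esri ASCII
#'
#' `write_esri_ascii()` writes a numeric or integer matrix as an `.asc`
#' grid (row 1 = northern edge); `read_esri_ascii()` reads one back.
#' `write_cost_raster()` writes the land-cover grid plus a JSON sidecar
#' recording class codes and costs; `read_cost_raster()` restores the
#' full `cost_raster`.
#'
#' @param m a matrix.
#' @param path file path.
#' @param cellsize cell size recorded in the header.
#' @param nodata NODATA value recorded in the header.
#' @return `read_esri_ascii()` returns a numeric matrix;
#'   `read_cost_raster()` a `cost_raster`.
#' @export
write_esri_ascii <- function(m, path, cellsize = 100, nodata = -9999) {
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           "xllcorner 0", "yllcorner 0",
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  ncols <- as.integer(strsplit(hdr[1], "\\s+")[[1]][2])
  nrows <- as.integer(strsplit(hdr[2], "\\s+")[[1]][2])
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  matrix(vals, nrows, ncols, byrow = TRUE)
}

#' @rdname write_esri_ascii
#' @param raster a `cost_raster`.
#' @param prefix output path prefix (writes `<prefix>.asc` and
#'   `<prefix>.json`).
#' @param config a [scenario_config()] for class costs on read.
#' @export
write_cost_raster <- function(raster, prefix, config = scenario_config()) {
  write_esri_ascii(raster$landcover, paste0(prefix, ".asc"),
                   cellsize = config$cell_size_m)
  jsonlite::write_json(
    list(classes = as.list(LANDCOVER_CLASSES),
         costs = as.list(setNames(class_costs(config),
                                  names(LANDCOVER_CLASSES)))),
    paste0(prefix, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_esri_ascii
#' @export
read_cost_raster <- function(prefix, config = scenario_config()) {
  lc <- read_esri_ascii(paste0(prefix, ".asc"))
  storage.mode(lc) <- "integer"
  build_cost_raster(lc, streams = NULL, config = config)
}
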