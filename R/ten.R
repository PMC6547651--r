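#' Build the time-expanded network
#'
#' Layered directed copy of the habitat network for a time horizon `T`:
#' each patch `v` gets `T + 1` copies `v_0, ..., v_T`; every habitat
#' edge `(u, v)` induces, for `t < T`, the two directed arcs
#' `(u_t, v_{t+1})` and `(v_t, u_{t+1})` carrying the original cost;
#' holdover arcs `(v_t, v_{t+1})` (cost 0) model staying put; and a
#' super source `Q` feeds the layer-0 copy of every initial source
#' habitat through a zero-cost arc. Each copy inherits the dispersal
#' capacity `u(v_t) = S_DIS * K(v)`.
#'
#' The construction has exactly `(T+1)*|V| + 1` nodes and
#' `T*(2|E| + |V|) + |H_start|` arcs.
#'
#' @param network a `habitat_network`.
#' @param sources non-empty set of initial source habitat ids.
#' @param T time horizon (integer >= 1).
#' @param config a [scenario_config()].
#' @param latest optional per-patch layer windows (integer vector in
#'   patch-table order): arcs touching copies of patch `v` after layer
#'   `latest[v]` are omitted. Used as a valid instance reduction when
#'   optimising towards fixed destinations — a copy later than
#'   `T - hopdistance(v, destination)` cannot lie on any flow path that
#'   reaches a destination copy within the horizon, and biomass at a
#'   window edge is simply discarded (which never enables anything).
#'   `NULL` keeps every copy.
#' @return a `ten` object: list with `network`, `n` (patches), `T`,
#'   `u` (per-patch dispersal capacity), `Q` (node id of the super
#'   source), `sources`, and `arcs` (data frame: `tail`, `head` node
#'   ids, `tail_v`, `head_v` patch indices, `t_from`, `cost`, `surv`
#'   = `1 - cost/C_max`, `type` in move/hold/source). Copy `(v, t)` has
#'   node id `t * n + v` with `v` the patch index (1..n).
#' @export
build_ten <- function(network, sources, T, config = scenario_config(),
                      latest = NULL) {
  if (T < 1) stop("time horizon T must be >= 1")
  T <- as.integer(T)
  if (length(sources) == 0) stop("at least one initial source is required")
  src_idx <- patch_index(network, sources)
  n <- nrow(network$patches)
  e <- network$edges
  if (nrow(e) && any(e$cost >= network$C_max))
    stop("edge cost at or above C_max; survival factor would vanish")
  copy_id <- function(v, t) t * n + v
  ei <- patch_index(network, e$from)
  ej <- patch_index(network, e$to)
  ts <- rep(0:(T - 1), each = nrow(e))
  mv_tail <- c(copy_id(rep(ei, T), ts), copy_id(rep(ej, T), ts))
  mv_head <- c(copy_id(rep(ej, T), ts + 1), copy_id(rep(ei, T), ts + 1))
  mv_cost <- rep(e$cost, 2 * T)
  th <- rep(0:(T - 1), each = n)
  hd_tail <- copy_id(rep(seq_len(n), T), th)
  hd_head <- copy_id(rep(seq_len(n), T), th + 1)
  Q <- (T + 1) * n + 1L
  arcs <- data.frame(
    tail = c(mv_tail, hd_tail, rep(Q, length(src_idx))),
    head = c(mv_head, hd_head, copy_id(src_idx, 0L)),
    tail_v = c(rep(ei, T), rep(ej, T),
               rep(seq_len(n), T), rep(NA_integer_, length(src_idx))),
    head_v = c(rep(ej, T), rep(ei, T),
               rep(seq_len(n), T), src_idx),
    t_from = c(rep(ts, 2), th, rep(NA_integer_, length(src_idx))),
    cost = c(mv_cost, rep(0, n * T), rep(0, length(src_idx))),
    type = c(rep("move", 2 * T * nrow(e)), rep("hold", n * T),
             rep("source", length(src_idx)))
  )
  arcs$surv <- 1 - arcs$cost / network$C_max
  if (is.null(latest)) {
    latest <- rep(T, n)
  } else {
    stopifnot(length(latest) == n)
    latest <- pmin(pmax(as.integer(latest), 0L), T)
    keep <- (arcs$type == "source") |
      (arcs$t_from <= latest[arcs$tail_v] &
         arcs$t_from + 1L <= latest[arcs$head_v])
    arcs <- arcs[keep, , drop = FALSE]
    rownames(arcs) <- NULL
  }
  structure(list(network = network, n = n, T = T,
                 T_SH = config$T_SH,
                 u = config$S_DIS * network$patches$K,
                 Q = Q, sources = sources, source_idx = src_idx,
                 latest = latest,
                 arcs = arcs),
            class = "ten")
}

#' @export
print.ten <- function(x, ...) {
  cat(sprintf("<ten> %d patches x %d layers: %d nodes (+Q), %d arcs\n",
              x$n, x$T + 1, (x$T + 1) * x$n, nrow(x$arcs)))
  invisible(x)
}

# node id of copy (v, t) in a ten
ten_copy <- function(ten, v, t) t * ten$n + v
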