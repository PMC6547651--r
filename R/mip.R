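#' Formulate the quickest-colonisation MIP
#'
#' Builds the mixed integer program on a time-expanded network whose
#' optimum is the minimum number of time steps needed to turn every
#' destination habitat into a source habitat. Variables: a flow
#' `f(e) >= 0` per arc, a binary `x(v_t)` per patch copy (1 = source
#' habitat at time t) and a binary `x(t)` per layer (1 = all
#' destinations colonised at layer t). The objective minimises
#' `sum_t t * x(t)`; the constraints are
#'
#' 1. `T_SH * x(v_t) <= sum of inflow f(e)` — a copy can only be a
#'    source if it holds at least the colonisation threshold;
#' 2. `f(v_{t-1}, v_t) = inflow of v_{t-1}` — all biomass of a patch is
#'    carried into the next layer on the holdover arc;
#' 3. `sum of outflow f(e) / (1 - C(e)/C_max) <= u(v) x(v_t) + inflow`
#'    — a source habitat emits at most its dispersal capacity
#'    `u(v) = S_DIS K(v)` on top of the biomass it carries forward,
#'    and emitted biomass is thinned by the cost-proportional mortality
#'    `C(e)/C_max` in transit;
#' 4. `f(Q, q_0) = T_SH` — every initial source habitat starts fully
#'    colonised;
#' 5. `|H_dest| x(t) <= sum of x(s_t) over destinations` — a layer
#'    counts only when every destination is a source in it;
#' 6. `sum_t x(t) >= 1` — the destinations must be colonised within the
#'    horizon.
#'
#' Constraints 1-3 range over patch copies (the super source `Q` only
#' carries the fixed injections of constraint 4); constraint 2 is imposed
#' for `t = 1..T`, the layers with a predecessor.
#'
#' Two optional, optimum-preserving strengthenings are applied by
#' default to help the branch-and-bound: monotonicity cuts
#' `x(v_t) <= x(v_{t+1})` (a colonised patch keeps its threshold
#' biomass on the holdover arc, so source status can always be carried
#' forward; the cuts only remove symmetric duplicates), and
#' earliest-layer fixing `x(v_t) = 0` for `t` below the hop distance
#' from the nearest initial source (biomass advances at most one edge
#' per layer). Both leave the set of achievable colonisation times —
#' and hence `t_star` — unchanged, and audited solutions still satisfy
#' the plain constraint system (1)-(6).
#'
#' @param ten a [build_ten()] time-expanded network.
#' @param H_dest destination patch ids (non-empty).
#' @param config a [scenario_config()].
#' @param strengthen add the monotonicity cuts.
#' @param earliest optional integer vector (one entry per patch, in
#'   patch-table order): a valid lower bound on the first layer at
#'   which each patch can be a source; copies below it are fixed to 0.
#' @return a `mip_instance`: the constraint system in sparse triplet
#'   form (`i`, `j`, `v`, row bounds `bl`/`bu`), objective `obj`,
#'   variable bounds and integrality flags, plus index bookkeeping
#'   (`nf` flow variables, then `nxv` copy binaries, then `nxt` layer
#'   binaries).
#' @export
build_mip <- function(ten, H_dest, config = scenario_config(),
                      strengthen = TRUE, earliest = NULL) {
  if (length(H_dest) == 0) stop("at least one destination is required")
  dest_idx <- patch_index(ten$network, H_dest)
  arcs <- ten$arcs
  if (any(arcs$surv <= 0))
    stop("arc with survival factor <= 0 (cost >= C_max); ",
         "must be prevented at network build")
  n <- ten$n; T <- ten$T
  nf <- nrow(arcs)
  nxv <- (T + 1) * n
  nxt <- T + 1
  ncol_ <- nf + nxv + nxt
  col_xv <- function(v, t) nf + t * n + v      # copy binaries
  col_xt <- function(t) nf + nxv + t + 1       # layer binaries
  copies <- seq_len(nxv)                        # node id == copy row id
  # row offsets per constraint family
  o1 <- 0L; o2 <- nxv; o3 <- nxv + n * T
  o4 <- o3 + nxv; o5 <- o4 + length(ten$source_idx); o6 <- o5 + nxt
  nrow_ <- o6 + 1L
  is_hold <- arcs$type == "hold"
  is_src <- arcs$type == "source"
  has_tail <- !is_src                      # arcs leaving a patch copy
  head_ok <- arcs$head                     # heads are always patch copies
  # (1): +T_SH x(copy) - inflow <= 0
  i1 <- c(o1 + head_ok, o1 + copies)
  j1 <- c(seq_len(nf), nf + copies)
  v1 <- c(rep(-1, nf), rep(config$T_SH, nxv))
  # (2): f(hold v_{t-1}->v_t) - inflow(v_{t-1}) = 0, rows indexed by
  # (v, t), t = 1..T -> row o2 + (t-1)*n + v. Inflow arcs of copy
  # (v, t-1) contribute -1 to row o2 + h, but only where that copy has
  # an outgoing holdover arc (at a window edge biomass is discarded)
  head_t <- (arcs$head - 1L) %/% n
  inprev <- head_t < ten$latest[arcs$head_v]
  hold_rows <- o2 + (arcs$t_from[is_hold]) * n + arcs$tail_v[is_hold]
  i2 <- c(hold_rows, o2 + arcs$head[inprev])
  j2 <- c(which(is_hold), which(inprev))
  v2 <- c(rep(1, sum(is_hold)), rep(-1, sum(inprev)))
  # (3): sum out f/surv - inflow - u(v) x(copy) <= 0
  tail_arcs <- which(has_tail)
  i3 <- c(o3 + arcs$tail[tail_arcs], o3 + head_ok, o3 + copies)
  j3 <- c(tail_arcs, seq_len(nf), nf + copies)
  v3 <- c(1 / arcs$surv[tail_arcs], rep(-1, nf),
          -ten$u[(copies - 1) %% n + 1])
  # (4): f(Q, q_0) = T_SH
  src_arcs <- which(is_src)
  i4 <- o4 + seq_along(src_arcs)
  j4 <- src_arcs
  v4 <- rep(1, length(src_arcs))
  # (5): |H_dest| x(t) - sum_dest x(s_t) <= 0
  tt <- 0:T
  i5 <- c(o5 + tt + 1, o5 + rep(tt + 1, each = length(dest_idx)))
  j5 <- c(col_xt(tt),
          col_xv(rep(dest_idx, length(tt)), rep(tt, each = length(dest_idx))))
  v5 <- c(rep(length(dest_idx), nxt), rep(-1, nxt * length(dest_idx)))
  # (6): sum_t x(t) >= 1
  i6 <- rep(o6 + 1L, nxt)
  j6 <- col_xt(tt)
  v6 <- rep(1, nxt)
  bl <- c(rep(-Inf, nxv), rep(0, n * T), rep(-Inf, nxv),
          rep(config$T_SH, length(src_arcs)), rep(-Inf, nxt), 1)
  bu <- c(rep(0, nxv), rep(0, n * T), rep(0, nxv),
          rep(config$T_SH, length(src_arcs)), rep(0, nxt), Inf)
  i7 <- j7 <- v7 <- numeric(0)
  if (strengthen && T >= 1) {
    # monotonicity cuts x(v_t) - x(v_{t+1}) <= 0, only between copies
    # inside the layer window (later copies are forced to 0 by their
    # lack of inflow, so a cut across the window edge would be invalid)
    vv <- rep(seq_len(n), T)
    tcut <- rep(0:(T - 1), each = n)
    kcut <- tcut + 1L <= ten$latest[vv]
    vv <- vv[kcut]; tcut <- tcut[kcut]
    ncut <- length(vv)
    rows7 <- nrow_ + seq_len(ncut)
    i7 <- c(rows7, rows7)
    j7 <- c(col_xv(vv, tcut), col_xv(vv, tcut + 1))
    v7 <- c(rep(1, ncut), rep(-1, ncut))
    bl <- c(bl, rep(-Inf, ncut))
    bu <- c(bu, rep(0, ncut))
    nrow_ <- nrow_ + ncut
  }
  obj <- c(rep(0, nf + nxv), tt)
  integrality <- c(rep(0L, nf), rep(1L, nxv + nxt))
  ub_xv <- rep(1, nxv)
  copy_t <- rep(0:T, each = n) # copy order t*n+v
  if (!is.null(earliest)) {
    stopifnot(length(earliest) == n)
    early <- pmin(pmax(earliest, 0L), T + 1L)
    ub_xv[copy_t < rep(early, T + 1)] <- 0
  }
  ub_xv[copy_t > rep(ten$latest, T + 1)] <- 0 # beyond the layer window
  structure(list(ten = ten, H_dest = H_dest, dest_idx = dest_idx,
                 T_SH = config$T_SH,
                 nf = nf, nxv = nxv, nxt = nxt,
                 n_var = ncol_, n_con = nrow_,
                 i = c(i1, i2, i3, i4, i5, i6, i7),
                 j = c(j1, j2, j3, j4, j5, j6, j7),
                 v = c(v1, v2, v3, v4, v5, v6, v7),
                 bl = bl, bu = bu, obj = obj,
                 lb = rep(0, ncol_),
                 ub = c(rep(Inf, nf), ub_xv, rep(1, nxt)),
                 integrality = integrality),
            class = "mip_instance")
}

#' @export
print.mip_instance <- function(x, ...) {
  cat(sprintf(
    "<mip_instance> %d vars (%d flows, %d copy + %d layer binaries), %d rows, %d nonzeros\n",
    x$n_var, x$nf, x$nxv, x$nxt, x$n_con, length(x$v)))
  invisible(x)
}

find_python <- function() {
  p <- getOption("colonet.python", "")
  if (!nzchar(p)) p <- Sys.getenv("COLONET_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p))
    stop("no python interpreter found for the HiGHS backend; set ",
         "options(colonet.python=...) or COLONET_PYTHON")
  p
}

#' Solve a quickest-colonisation MIP
#'
#' Solves the instance with the HiGHS solver (through scipy's `milp`
#' front-end; MIP gap 0, so integrality of the objective proves
#' optimality) and re-audits the returned solution against constraints
#' (1)-(6) by direct arithmetic, independent of the solver, before
#' reporting it. The minimum colonisation time is read as
#' `min{t : x(t) = 1}` (robust against the zero objective coefficient
#' of `x(0)`).
#'
#' @param instance a [build_mip()] instance.
#' @param solver backend name; `"highs"` is the only built-in.
#' @param time_limit seconds (`Inf` for none). A timeout is reported as
#'   status `"timeout"`, never as a silent wrong answer.
#' @param audit re-verify the solution at tolerance `1e-6` (stop on
#'   violation).
#' @return a `mip_solution`: `status` (`"optimal"`, `"infeasible"` —
#'   meaning the destinations are not colonisable within the horizon —
#'   or `"timeout"`), and when optimal `t_star`, `flows` (per arc),
#'   `x_copies` (n x (T+1) binary matrix), `x_layers`, `layer_hits`
#'   and `objective`.
#' @export
solve_mip <- function(instance, solver = "highs", time_limit = Inf,
                      audit = TRUE) {
  if (!identical(solver, "highs"))
    stop("unknown solver '", solver, "'; available: highs")
  dir <- tempfile("milp")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  wbin <- function(x, name, what) {
    con <- file(file.path(dir, name), "wb")
    on.exit(close(con), add = TRUE)
    if (what == "integer") writeBin(as.integer(x), con, size = 4L)
    else writeBin(as.double(x), con, size = 8L)
  }
  wbin(instance$i - 1L, "ai.bin", "integer")  # 0-based for scipy
  wbin(instance$j - 1L, "aj.bin", "integer")
  wbin(instance$v, "av.bin", "double")
  wbin(instance$bl, "bl.bin", "double")
  wbin(instance$bu, "bu.bin", "double")
  wbin(instance$obj, "c.bin", "double")
  wbin(instance$lb, "lb.bin", "double")
  wbin(instance$ub, "ub.bin", "double")
  wbin(instance$integrality, "int.bin", "integer")
  jsonlite::write_json(
    list(n_var = instance$n_var, n_con = instance$n_con,
         nnz = length(instance$v),
         time_limit = if (is.finite(time_limit)) time_limit else NULL,
         mip_rel_gap = 0),
    file.path(dir, "header.json"), auto_unbox = TRUE, null = "null")
  script <- system.file("python", "solve_milp.py", package = "colonet",
                        mustWork = TRUE)
  out <- system2(find_python(), c(shQuote(script), shQuote(dir)),
                 stdout = TRUE, stderr = TRUE)
  rc <- attr(out, "status")
  if (!is.null(rc) && rc != 0)
    stop("MILP backend failed (exit ", rc, "):\n",
         paste(out, collapse = "\n"))
  res <- jsonlite::read_json(file.path(dir, "result.json"),
                             simplifyVector = TRUE)
  if (identical(res$status_class, "infeasible"))
    return(structure(list(status = "infeasible"), class = "mip_solution"))
  if (identical(res$status_class, "timeout"))
    return(structure(list(status = "timeout"), class = "mip_solution"))
  if (!identical(res$status_class, "optimal"))
    stop("MILP backend returned status '", res$status_class, "': ",
         res$message)
  con <- file(file.path(dir, "x.bin"), "rb")
  x <- readBin(con, "double", n = instance$n_var, size = 8L)
  close(con)
  nf <- instance$nf
  flows <- x[seq_len(nf)]
  xv <- round(x[nf + seq_len(instance$nxv)])
  xt <- round(x[nf + instance$nxv + seq_len(instance$nxt)])
  if (max(abs(x[-seq_len(nf)] - round(x[-seq_len(nf)]))) > 1e-5)
    stop("solver returned non-integral binaries")
  sol <- structure(
    list(status = "optimal",
         t_star = min(which(xt == 1)) - 1L,
         flows = flows,
         x_copies = matrix(xv, instance$ten$n, instance$ten$T + 1,
                           dimnames = list(instance$ten$network$patches$id,
                                           0:instance$ten$T)),
         x_layers = xt,
         layer_hits = which(xt == 1) - 1L,
         objective = res$fun),
    class = "mip_solution")
  if (audit) {
    chk <- audit_solution(instance, sol)
    if (!chk$ok)
      stop("solver solution violates the model constraints:\n",
           paste(utils::capture.output(print(chk$violations)),
                 collapse = "\n"))
  }
  sol
}

#' @export
print.mip_solution <- function(x, ...) {
  if (x$status != "optimal") {
    cat("<mip_solution>", x$status, "\n")
  } else {
    cat(sprintf("<mip_solution> optimal: t* = %d (layer hits: %s)\n",
                x$t_star, paste(x$layer_hits, collapse = ", ")))
  }
  invisible(x)
}

#' Audit a MIP solution against constraints (1)-(6)
#'
#' Recomputes every constraint by direct arithmetic on the arc table and
#' the returned flows/binaries — independent of the solver and of the
#' sparse-matrix assembly — and reports violations beyond `tol`.
#'
#' @param instance a [build_mip()] instance.
#' @param solution a [solve_mip()] solution with status `"optimal"`.
#' @param tol numeric tolerance.
#' @return list with `ok` (logical) and `violations` (data frame:
#'   `constraint`, `where`, `amount`).
#' @export
audit_solution <- function(instance, solution, tol = 1e-6) {
  stopifnot(solution$status == "optimal")
  ten <- instance$ten
  arcs <- ten$arcs
  f <- solution$flows
  n <- ten$n; T <- ten$T
  nxv <- (T + 1) * n
  xv <- as.vector(solution$x_copies)     # copy id order
  xt <- solution$x_layers
  T_SH <- instance$T_SH
  inflow <- numeric(nxv)
  agg <- rowsum(f, arcs$head)
  inflow[as.integer(rownames(agg))] <- agg
  outsc <- numeric(nxv)
  ht <- arcs$type != "source"
  agg2 <- rowsum(f[ht] / arcs$surv[ht], arcs$tail[ht])
  outsc[as.integer(rownames(agg2))] <- agg2
  viol <- list()
  add <- function(constraint, where, amount) {
    viol[[length(viol) + 1]] <<- data.frame(constraint = constraint,
                                            where = where, amount = amount)
  }
  # (1)
  bad <- which(T_SH * xv - inflow > tol)
  for (b in bad) add("1", paste0("copy ", b), T_SH * xv[b] - inflow[b])
  # (2)
  hold <- arcs$type == "hold"
  lhs <- f[hold]
  prev_copy <- arcs$tail[hold]
  bad <- which(abs(lhs - inflow[prev_copy]) > tol)
  for (b in bad) add("2", paste0("hold from copy ", prev_copy[b]),
                     lhs[b] - inflow[prev_copy[b]])
  # (3)
  u_copy <- ten$u[(seq_len(nxv) - 1) %% n + 1]
  bad <- which(outsc - u_copy * xv - inflow > tol)
  for (b in bad) add("3", paste0("copy ", b),
                     outsc[b] - u_copy[b] * xv[b] - inflow[b])
  # (4)
  sa <- which(arcs$type == "source")
  bad <- which(abs(f[sa] - T_SH) > tol)
  for (b in bad) add("4", paste0("source arc to patch ",
                                 arcs$head_v[sa][b]), f[sa][b] - T_SH)
  # (5)
  xvm <- matrix(xv, n, T + 1)
  dsum <- colSums(xvm[instance$dest_idx, , drop = FALSE])
  bad <- which(length(instance$dest_idx) * xt - dsum > tol)
  for (b in bad) add("5", paste0("layer ", b - 1),
                     length(instance$dest_idx) * xt[b] - dsum[b])
  # (6)
  if (sum(xt) < 1 - tol) add("6", "sum over layers", 1 - sum(xt))
  viol <- if (length(viol)) do.call(rbind, viol)
          else data.frame(constraint = character(0), where = character(0),
                          amount = numeric(0))
  list(ok = nrow(viol) == 0, violations = viol)
}

mip_var_names <- function(instance) {
  ten <- instance$ten
  arcs <- ten$arcs
  ids <- ten$network$patches$id
  tailn <- ifelse(arcs$type == "source", "Q", ids[arcs$tail_v])
  fn <- paste0("f_", tailn, "_", ids[arcs$head_v], "_",
               ifelse(is.na(arcs$t_from), 0L, arcs$t_from))
  n <- ten$n; T <- ten$T
  xvn <- paste0("x_", rep(ids, T + 1), "_", rep(0:T, each = n))
  xtn <- paste0("xl_", 0:T)
  c(fn, xvn, xtn)
}

#' Export a MIP instance as LP or MPS
#'
#' Plain-text CPLEX-LP / free-MPS export with the deterministic variable
#' naming scheme `f_<tail>_<head>_<t>`, `x_<patch>_<t>`, `xl_<t>`, so
#' instances can be solved or inspected with any external MILP solver.
#'
#' @param instance a [build_mip()] instance.
#' @param path output file.
#' @export
write_lp <- function(instance, path) {
  nm <- mip_var_names(instance)
  ord <- order(instance$i, instance$j)
  i <- instance$i[ord]; j <- instance$j[ord]; v <- instance$v[ord]
  terms <- paste0(ifelse(v >= 0, " + ", " - "), abs(v), " ", nm[j])
  rows <- split(terms, i)
  lines <- c("Minimize",
             paste0(" obj:",
                    paste0(ifelse(instance$obj != 0,
                                  paste0(" + ", instance$obj, " ", nm),
                                  ""), collapse = "")),
             "Subject To")
  rid <- as.integer(names(rows))
  for (k in seq_along(rows)) {
    r <- rid[k]
    expr <- paste0(rows[[k]], collapse = "")
    if (is.finite(instance$bl[r]) && is.finite(instance$bu[r]) &&
        instance$bl[r] == instance$bu[r]) {
      lines <- c(lines, paste0(" c", r, ":", expr, " = ", instance$bl[r]))
    } else if (is.finite(instance$bu[r])) {
      lines <- c(lines, paste0(" c", r, ":", expr, " <= ", instance$bu[r]))
    } else {
      lines <- c(lines, paste0(" c", r, ":", expr, " >= ", instance$bl[r]))
    }
  }
  bin <- which(instance$integrality == 1L)
  lines <- c(lines, "Bounds",
             paste0(" 0 <= ", nm[seq_len(instance$nf)], " <= +inf"),
             "Binaries", paste(" ", nm[bin]), "End")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lp
#' @export
write_mps <- function(instance, path) {
  nm <- mip_var_names(instance)
  eq <- is.finite(instance$bl) & is.finite(instance$bu) &
    instance$bl == instance$bu
  le <- !eq & is.finite(instance$bu)
  sense <- ifelse(eq, "E", ifelse(le, "L", "G"))
  rhs <- ifelse(eq | le, instance$bu, instance$bl)
  lines <- c("NAME colonet_mip", "ROWS", " N obj",
             paste0(" ", sense, " c", seq_len(instance$n_con)))
  ord <- order(instance$j, instance$i)
  j <- instance$j[ord]; i <- instance$i[ord]; v <- instance$v[ord]
  col_entries <- split(paste0("    ", nm[j], " c", i, " ", v), j)
  lines <- c(lines, "COLUMNS")
  intg <- instance$integrality
  in_int <- FALSE
  for (cidx in seq_len(instance$n_var)) {
    want_int <- intg[cidx] == 1L
    if (want_int && !in_int) {
      lines <- c(lines, "    MARKER M1 'MARKER' 'INTORG'")
      in_int <- TRUE
    }
    if (!want_int && in_int) {
      lines <- c(lines, "    MARKER M2 'MARKER' 'INTEND'")
      in_int <- FALSE
    }
    ent <- col_entries[[as.character(cidx)]]
    if (!is.null(ent)) lines <- c(lines, ent)
    if (instance$obj[cidx] != 0)
      lines <- c(lines, paste0("    ", nm[cidx], " obj ",
                               instance$obj[cidx]))
  }
  if (in_int) lines <- c(lines, "    MARKER M3 'MARKER' 'INTEND'")
  lines <- c(lines, "RHS",
             paste0("    rhs c", which(rhs != 0), " ", rhs[rhs != 0]),
             "BOUNDS",
             paste0(" BV bnd ", nm[intg == 1L]),
             "ENDATA")
  writeLines(lines, path)
  invisible(path)
}
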