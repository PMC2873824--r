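## Path-directed subdivision tree (PDST) search adapted to articulated
## protein models. Samples are pathway segments; a deterministic score
## (priority / cell volume) over a binary subdivision of the projected
## feature space drives coverage, with goal biasing in a fraction of the
## iterations and iterative restart cycles from the best conformation.

#' Planner configuration
#'
#' @param iterations_per_cycle iteration cap per PDST cycle.
#' @param cycles number of restart cycles; each restarts the tree from the
#'   best conformation found so far.
#' @param bias_fraction fraction of iterations that select from the pool of
#'   segments ending nearest the goal instead of by the coverage score.
#' @param bias_pool size of that pool.
#' @param delta_step dihedral increment per propagation step (radians).
#' @param max_steps maximum steps per propagation.
#' @param tau success threshold on the normalized distance to the goal.
#' @param cycle_threshold_fraction a cycle ends early once some conformation
#'   gets below this fraction of the cycle-start distance to the goal.
#' @param seed RNG seed; all stochastic choices derive from one stream.
#' @return list of class `planner_config`.
#' @export
planner_config <- function(iterations_per_cycle = 20000L, cycles = 3L,
                           bias_fraction = 0.10, bias_pool = 10L,
                           delta_step = deg2rad(2), max_steps = 20L,
                           tau = 0.16, cycle_threshold_fraction = 0.85,
                           seed = 1L) {
  stopifnot(bias_fraction >= 0, bias_fraction <= 1, tau > 0, tau < 1,
            max_steps >= 1L, iterations_per_cycle >= 1L, cycles >= 1L)
  out <- list(iterations_per_cycle = as.integer(iterations_per_cycle),
              cycles = as.integer(cycles), bias_fraction = bias_fraction,
              bias_pool = as.integer(bias_pool), delta_step = delta_step,
              max_steps = as.integer(max_steps), tau = tau,
              cycle_threshold_fraction = cycle_threshold_fraction,
              seed = as.integer(seed))
  class(out) <- "planner_config"
  out
}

## ---- planner state -------------------------------------------------------

#' Create a fresh PDST state
#'
#' Exposed so the selection/subdivision bookkeeping can be driven (and
#' tested) independently of the full search loop.
#'
#' @param root_conf the conformation seeding the tree (a pathway of length
#'   zero).
#' @param goal goal `conformation`.
#' @param mparams,eparams metric and energy parameters.
#' @param config a `planner_config`.
#' @param energy_fn optional override `function(conformation) -> kcal/mol`;
#'   defaults to [compute_energy()] total.
#' @param root_parent optional `list(seg, pos)` linking this tree's root to
#'   a segment of a previous cycle, so path replay crosses cycles.
#' @param store optional shared segment store (environment) reused across
#'   cycles.
#' @return an environment holding the planner state.
#' @export
pdst_state <- function(root_conf, goal, mparams = metric_params(),
                       eparams = energy_params(), config = planner_config(),
                       energy_fn = NULL, root_parent = NULL, store = NULL) {
  st <- if (is.null(store)) new.env(parent = emptyenv()) else store
  st$topo <- root_conf$topology
  st$goal <- goal
  st$mparams <- mparams
  st$eparams <- eparams
  st$config <- config
  st$energy_fn <- if (is.null(energy_fn))
    function(conf) compute_energy(conf, eparams)$total else energy_fn
  if (is.null(st$segs)) {
    st$segs <- list(); st$pri <- numeric(0); st$seg_cell <- integer(0)
    st$end_dist <- numeric(0); st$alive <- logical(0)
    st$best_seg <- NA_integer_; st$best_pos <- NA_integer_
    st$best_dist <- Inf
  }
  f0 <- feature_vector(root_conf, goal, mparams)
  st$d <- length(f0)
  ctr <- f0 / 2
  half <- pmax(abs(f0 / 2) * 2, 1e-3)     # bounding box of {F(root), 0}, x2
  st$lo0 <- ctr - half
  st$hi0 <- ctr + half
  st$cell_lo <- matrix(st$lo0, 1L, st$d, byrow = TRUE)
  st$cell_hi <- matrix(st$hi0, 1L, st$d, byrow = TRUE)
  st$cell_depth <- 0L
  st$cell_vol <- prod(st$hi0 - st$lo0)
  st$ncell <- 1L
  st$selections <- 0L
  st$cells_created <- 0L
  ## deactivate earlier cycles' segments, then seed the new root segment
  st$alive[] <- FALSE
  rid <- new_segment(st,
                     parent = if (is.null(root_parent)) NA_integer_
                              else root_parent$seg,
                     parent_pos = if (is.null(root_parent)) NA_integer_
                                  else root_parent$pos,
                     confs = list(root_conf$xyz),
                     moves = list(), proj = matrix(f0, 1L),
                     priority = 1)
  st$root_seg <- rid
  st
}

## register one segment (possibly splitting it across cells); returns the id
## of the first piece.
new_segment <- function(st, parent, parent_pos, confs, moves, proj,
                        priority) {
  grow_box(st, proj)
  cell_of <- locate_cells(st, proj)
  runs <- rle(cell_of)
  first_id <- NA_integer_
  at <- 0L
  prev_id <- NA_integer_
  for (k in seq_along(runs$lengths)) {
    idxs <- (at + 1L):(at + runs$lengths[k])
    at <- at + runs$lengths[k]
    id <- length(st$segs) + 1L
    st$segs[[id]] <- list(
      id = id,
      parent = if (k == 1L) parent else prev_id,
      parent_pos = if (k == 1L) parent_pos
                   else length(st$segs[[prev_id]]$confs),
      confs = confs[idxs],
      moves = if (length(moves)) moves[idxs] else list(),
      proj = proj[idxs, , drop = FALSE])
    st$pri[id] <- priority
    st$seg_cell[id] <- runs$values[k]
    st$end_dist[id] <- seg_dist(st, proj[idxs[length(idxs)], ])
    st$alive[id] <- TRUE
    if (k == 1L) first_id <- id
    prev_id <- id
  }
  first_id
}

seg_dist <- function(st, fvec) sqrt(sum(fvec^2))

## cell index containing each projection row (cells partition the root box;
## lower-closed, upper-open except at the root box top).
locate_cells <- function(st, proj) {
  n <- nrow(proj)
  out <- integer(n)
  for (r in seq_len(n)) {
    p <- proj[r, ]
    for (cl in seq_len(st$ncell)) {
      lo <- st$cell_lo[cl, ]; hi <- st$cell_hi[cl, ]
      ok <- all(p >= lo & (p < hi | (p <= hi & hi >= st$hi0 - 1e-12)))
      if (ok) { out[r] <- cl; break }
    }
    if (out[r] == 0L) stop("projection point escaped the cell partition")
  }
  out
}

## extend the root box (and the boundary cells) to cover points outside it.
grow_box <- function(st, proj) {
  pmaxs <- apply(proj, 2L, max)
  pmins <- apply(proj, 2L, min)
  for (k in seq_len(st$d)) {
    if (pmaxs[k] > st$hi0[k]) {
      on_edge <- st$cell_hi[, k] >= st$hi0[k] - 1e-12
      st$cell_hi[on_edge, k] <- pmaxs[k]
      st$hi0[k] <- pmaxs[k]
    }
    if (pmins[k] < st$lo0[k]) {
      on_edge <- st$cell_lo[, k] <= st$lo0[k] + 1e-12
      st$cell_lo[on_edge, k] <- pmins[k]
      st$lo0[k] <- pmins[k]
    }
  }
  st$cell_vol <- apply(st$cell_hi - st$cell_lo, 1L, prod)
  invisible(st)
}

#' Select a segment for propagation
#'
#' Deterministic coverage scoring: the live segment minimizing
#' priority / cell-volume (ties: lowest id), after which its priority is
#' updated to `2 * priority + 1` so every segment is eventually selected.
#' In biased iterations the segment is drawn uniformly from the pool of
#' live segments whose end conformations are nearest the goal.
#'
#' @param st planner state from [pdst_state()].
#' @param bias_on logical: use goal biasing for this selection.
#' @return the selected segment id.
#' @export
select_segment <- function(st, bias_on = FALSE) {
  ids <- which(st$alive)
  stopifnot(length(ids) > 0L)
  if (bias_on) {
    pool <- ids[order(st$end_dist[ids], ids)]
    pool <- pool[seq_len(min(st$config$bias_pool, length(pool)))]
    sel <- pool[sample.int(length(pool), 1L)]
  } else {
    score <- st$pri[ids] / st$cell_vol[st$seg_cell[ids]]
    sel <- ids[order(score, ids)][1L]
  }
  st$pri[sel] <- 2 * st$pri[sel] + 1
  st$selections <- st$selections + 1L
  sel
}

#' Subdivide the cell containing a segment
#'
#' Splits the cell at the midpoint of the depth-cycling dimension into two
#' cells and reassigns member segments; any segment whose projection spans
#' the new boundary is split into chained pieces so that no sample spans
#' more than one cell.
#'
#' @param st planner state.
#' @param cell_id the cell to split.
#' @return invisibly, the id of the newly created cell.
#' @export
subdivide <- function(st, cell_id) {
  dim_k <- st$cell_depth[cell_id] %% st$d + 1L
  lo <- st$cell_lo[cell_id, ]; hi <- st$cell_hi[cell_id, ]
  mid <- (lo[dim_k] + hi[dim_k]) / 2
  new_id <- st$ncell + 1L
  st$cell_lo <- rbind(st$cell_lo, replace(lo, dim_k, mid),
                      deparse.level = 0)
  st$cell_hi <- rbind(st$cell_hi, hi, deparse.level = 0)
  st$cell_hi[cell_id, dim_k] <- mid
  st$cell_depth[cell_id] <- st$cell_depth[cell_id] + 1L
  st$cell_depth[new_id] <- st$cell_depth[cell_id]
  st$ncell <- new_id
  st$cell_vol <- apply(st$cell_hi - st$cell_lo, 1L, prod)
  st$cells_created <- st$cells_created + 1L

  members <- which(st$alive & st$seg_cell == cell_id)
  for (id in members) {
    seg <- st$segs[[id]]
    side <- locate_cells(st, seg$proj)
    if (all(side == side[1L])) {
      st$seg_cell[id] <- side[1L]
      next
    }
    split_segment(st, id, side)
  }
  invisible(new_id)
}

## split segment `id` into chained pieces along runs of `cell_of`.
split_segment <- function(st, id, cell_of) {
  seg <- st$segs[[id]]
  ## children pointing into this segment must be relinked afterwards
  kids <- which(vapply(st$segs, function(s)
    isTRUE(s$parent == id), TRUE))
  runs <- rle(cell_of)
  at <- runs$lengths[1L]
  ## first run stays under the original id
  st$segs[[id]]$confs <- seg$confs[seq_len(at)]
  st$segs[[id]]$moves <- seg$moves[seq_len(at)]
  st$segs[[id]]$proj <- seg$proj[seq_len(at), , drop = FALSE]
  st$seg_cell[id] <- runs$values[1L]
  st$end_dist[id] <- seg_dist(st, seg$proj[at, ])
  prev_id <- id
  remap <- rep.int(id, length(cell_of))
  for (k in seq_along(runs$lengths)[-1L]) {
    idxs <- (at + 1L):(at + runs$lengths[k])
    at <- at + runs$lengths[k]
    nid <- length(st$segs) + 1L
    st$segs[[nid]] <- list(
      id = nid, parent = prev_id,
      parent_pos = length(st$segs[[prev_id]]$confs),
      confs = seg$confs[idxs], moves = seg$moves[idxs],
      proj = seg$proj[idxs, , drop = FALSE])
    st$pri[nid] <- st$pri[id]
    st$seg_cell[nid] <- runs$values[k]
    st$end_dist[nid] <- seg_dist(st, seg$proj[idxs[length(idxs)], ])
    st$alive[nid] <- TRUE
    remap[idxs] <- nid
    prev_id <- nid
  }
  ## position of each original conformation within its piece
  pos_in_piece <- unlist(lapply(runs$lengths, seq_len))
  ## relink children (and cycle roots) that referenced the old numbering
  for (kid in kids) {
    p <- st$segs[[kid]]$parent_pos
    st$segs[[kid]]$parent <- remap[p]
    st$segs[[kid]]$parent_pos <- pos_in_piece[p]
  }
  ## keep best-conformation bookkeeping pointing at the right piece
  if (!is.na(st$best_seg) && st$best_seg == id) {
    p <- st$best_pos
    st$best_seg <- remap[p]
    st$best_pos <- pos_in_piece[p]
  }
  invisible(remap)
}

#' Propagate a new pathway segment
#'
#' From a uniformly random conformation on the given segment, applies a
#' random DOF rotation (random sign) in `delta_step` increments, evaluating
#' the energy gate at each step; stops before the first rejected step or at
#' `max_steps`. A step at or above the repair threshold triggers the short
#' steepest-descent repair before re-gating. Returns the id of the new
#' segment (>= 1 accepted conformation) or NA on rejection.
#'
#' @param st planner state.
#' @param seg_id segment to propagate from.
#' @param iteration current iteration (new segments take it as priority).
#' @return new segment id or `NA`.
#' @export
propagate <- function(st, seg_id, iteration) {
  seg <- st$segs[[seg_id]]
  pos <- sample.int(length(seg$confs), 1L)
  dof_i <- sample.int(length(st$topo$dofs), 1L)
  sgn <- if (stats::runif(1L) < 0.5) 1 else -1
  dof <- st$topo$dofs[[dof_i]]
  dof_name <- names(st$topo$dofs)[dof_i]
  cur <- conformation(st$topo, xyz = seg$confs[[pos]])
  confs <- list(); moves <- list(); proj <- NULL
  for (step in seq_len(st$config$max_steps)) {
    trial <- apply_dihedral(cur, dof, sgn * st$config$delta_step)
    e <- st$energy_fn(trial)
    gate <- energy_gate(e, st$e_start)
    repaired <- FALSE
    if (!gate$accept && gate$repair) {
      trial <- local_minimize(trial, dof$distal, st$eparams)
      e <- st$energy_fn(trial)
      gate <- energy_gate(e, st$e_start)
      repaired <- TRUE
    }
    if (!gate$accept) break
    cur <- trial
    confs[[step]] <- trial$xyz
    moves[[step]] <- list(dof = dof_name, delta = sgn * st$config$delta_step,
                          repaired = repaired)
    proj <- rbind(proj, feature_vector(trial, st$goal, st$mparams))
  }
  if (length(confs) == 0L) return(NA_integer_)
  nid <- new_segment(st, parent = seg_id, parent_pos = pos,
                     confs = confs, moves = moves, proj = proj,
                     priority = iteration)
  ## track the best conformation over the whole run
  dists <- sqrt(rowSums(proj^2))
  b <- which.min(dists)
  if (dists[b] < st$best_dist) {
    st$best_dist <- dists[b]
    loc <- locate_piece(st, nid, b)
    st$best_seg <- loc$seg; st$best_pos <- loc$pos
  }
  nid
}

## the (piece id, position) holding the k-th conformation of a segment that
## may have been split into chained pieces at insertion.
locate_piece <- function(st, first_id, k) {
  id <- first_id
  repeat {
    m <- length(st$segs[[id]]$confs)
    if (k <= m) return(list(seg = id, pos = k))
    k <- k - m
    ## the next piece is the one whose parent is `id`
    nxt <- which(vapply(st$segs, function(s)
      identical(s$parent, id), TRUE))
    nxt <- nxt[nxt > id][1L]
    if (is.na(nxt)) stop("internal: chained piece not found")
    id <- nxt
  }
}

#' Run the PDST planner
#'
#' Searches for a low-energy pathway from `start` to `goal`. Each cycle
#' seeds a fresh subdivision tree from the best conformation found so far
#' and iterates select-propagate-subdivide until its iteration cap, ending
#' early once some conformation is closer to the goal than
#' `cycle_threshold_fraction` times the cycle-start distance. The search
#' succeeds when the normalized distance drops to `tau` or below. Fully
#' reproducible for a fixed seed.
#'
#' @param start,goal `conformation` end states over one topology.
#' @param mparams,eparams metric and energy parameters.
#' @param config a `planner_config`.
#' @param energy_fn optional energy override (see [pdst_state()]).
#' @return list of class `planner_result`: `success`,
#'   `best_normalized_distance`, `best` conformation, `moves` (replayable
#'   move records from the start), `path` (conformations along the best
#'   pathway), `cycles` (per-cycle statistics), `e_start`.
#' @export
run_pdst <- function(start, goal, mparams = metric_params(),
                     eparams = energy_params(), config = planner_config(),
                     energy_fn = NULL) {
  d0 <- conf_distance(start, goal, goal, mparams)
  if (d0 <= 0) stop("start and goal coincide under the metric")
  set.seed(config$seed)
  efn <- if (is.null(energy_fn))
    function(conf) compute_energy(conf, eparams)$total else energy_fn
  e_start <- efn(start)

  store <- NULL
  root <- start
  root_parent <- NULL
  stats_cycles <- list()
  success <- FALSE
  st <- NULL
  for (cy in seq_len(config$cycles)) {
    st <- pdst_state(root, goal, mparams, eparams, config, energy_fn = efn,
                     root_parent = root_parent, store = store)
    store <- st
    st$e_start <- e_start
    cycle_start_dist <- seg_dist(st, feature_vector(root, goal, mparams))
    sel0 <- st$selections
    it <- 0L
    while (it < config$iterations_per_cycle) {
      it <- it + 1L
      bias_on <- stats::runif(1L) < config$bias_fraction
      sel <- select_segment(st, bias_on)
      cell <- st$seg_cell[sel]
      propagate(st, sel, it)
      subdivide(st, cell)
      if (st$best_dist <= config$tau * d0) { success <- TRUE; break }
      if (st$best_dist <=
          config$cycle_threshold_fraction * cycle_start_dist) break
    }
    stats_cycles[[cy]] <- list(iterations = it,
                               selections = st$selections - sel0,
                               cells = st$ncell,
                               best_distance = st$best_dist,
                               best_normalized = st$best_dist / d0)
    if (success) break
    if (is.finite(st$best_dist) && st$best_dist < cycle_start_dist) {
      root <- conformation(st$topo,
                           xyz = st$segs[[st$best_seg]]$confs[[st$best_pos]])
      root_parent <- list(seg = st$best_seg, pos = st$best_pos)
    }
  }

  best_conf <- if (is.finite(st$best_dist))
    conformation(st$topo, xyz = st$segs[[st$best_seg]]$confs[[st$best_pos]])
  else start
  moves <- collect_moves(st, st$best_seg, st$best_pos)
  out <- list(success = success,
              best_normalized_distance = st$best_dist / d0,
              best = best_conf, moves = moves,
              path = NULL, cycles = stats_cycles, e_start = e_start,
              config = config, state = st)
  out$path <- replay_moves(st$topo, moves, eparams, keep = "all")
  class(out) <- "planner_result"
  out
}

## flatten the move records from the tree root(s) down to (seg, pos).
collect_moves <- function(st, seg, pos) {
  if (is.na(seg)) return(list())
  out <- list()
  repeat {
    s <- st$segs[[seg]]
    take <- if (length(s$moves) >= pos && pos >= 1L) s$moves[seq_len(pos)]
            else list()
    out <- c(take, out)
    if (is.na(s$parent)) break
    pos <- s$parent_pos
    seg <- s$parent
  }
  out
}

#' Replay a move list from the start conformation
#'
#' Deterministically re-applies recorded planner moves (dihedral steps and,
#' where flagged, the steepest-descent repair) from the topology's start
#' state.
#'
#' @param topology a `pathway_topology`.
#' @param moves move records as stored in a `planner_result`.
#' @param eparams energy parameters (needed to replay repairs).
#' @param keep "all" for the full conformation list, "last" for the final
#'   conformation only.
#' @return list of conformations (including the start), or one conformation.
#' @export
replay_moves <- function(topology, moves, eparams = energy_params(),
                         keep = c("all", "last")) {
  keep <- match.arg(keep)
  conf <- start_conformation(topology)
  out <- list(conf)
  for (mv in moves) {
    conf <- apply_dihedral(conf, mv$dof, mv$delta)
    if (isTRUE(mv$repaired)) {
      d <- topology$dofs[[mv$dof]]
      conf <- local_minimize(conf, d$distal, eparams)
    }
    if (keep == "all") out[[length(out) + 1L]] <- conf
  }
  if (keep == "last") conf else out
}

#' @export
print.planner_result <- function(x, ...) {
  cat(sprintf(paste0("planner_result: %s, best normalized distance %.4f, ",
                     "%d cycle(s), path length %d\n"),
              if (x$success) "success" else "no success",
              x$best_normalized_distance, length(x$cycles),
              length(x$path)))
  invisible(x)
}
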