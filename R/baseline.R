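## Metropolis random-walk comparator. It optimizes the similarity score
## (distance to the goal) rather than the energy; the energy gate only
## filters out infeasible conformations. Move generation and gating share
## the planner's code paths so the two methods differ only in their search
## strategy.

#' Metropolis acceptance on the similarity score
#'
#' With improvement `dS = s_prev - s_new`, the move is always accepted when
#' `dS >= 0` (all "good" steps) and otherwise accepted with probability
#' `exp(dS / temperature)`, so only a small fraction of worsening steps
#' pass.
#'
#' @param s_prev,s_new similarity scores (distance to goal) before/after.
#' @param temperature score-units scale of the acceptance (default 1).
#' @return logical.
#' @export
accept_move <- function(s_prev, s_new, temperature = 1) {
  ds <- s_prev - s_new
  if (ds >= 0) return(TRUE)
  stats::runif(1L) < exp(ds / temperature)
}

#' Run the random-walk baseline
#'
#' At each iteration a single `delta_step` rotation of a uniformly random
#' DOF (random sign) is proposed from the current conformation, gated on
#' the energy (same gate as the planner, relative to the start energy) and
#' then accepted or rejected by the Metropolis criterion on the distance to
#' the goal. Terminates on the planner's success threshold or after
#' `cycles * iterations_per_cycle` proposals.
#'
#' @inheritParams run_pdst
#' @param temperature acceptance temperature (score units).
#' @return list of class `planner_result` (same fields as [run_pdst()];
#'   `cycles` holds one entry with acceptance counts).
#' @export
run_random_walk <- function(start, goal, mparams = metric_params(),
                            eparams = energy_params(),
                            config = planner_config(), energy_fn = NULL,
                            temperature = 1) {
  d0 <- conf_distance(start, goal, goal, mparams)
  if (d0 <= 0) stop("start and goal coincide under the metric")
  set.seed(config$seed)
  efn <- if (is.null(energy_fn))
    function(conf) compute_energy(conf, eparams)$total else energy_fn
  e_start <- efn(start)
  topo <- start$topology
  budget <- config$cycles * config$iterations_per_cycle

  cur <- start
  s_cur <- d0
  moves <- list()
  best <- cur; best_s <- s_cur; best_moves <- list()
  trace <- s_cur
  n_acc <- 0L; n_gate_rej <- 0L
  success <- FALSE
  it <- 0L
  while (it < budget) {
    it <- it + 1L
    dof_i <- sample.int(length(topo$dofs), 1L)
    sgn <- if (stats::runif(1L) < 0.5) 1 else -1
    delta <- sgn * config$delta_step
    trial <- apply_dihedral(cur, topo$dofs[[dof_i]], delta)
    e <- efn(trial)
    if (!energy_gate(e, e_start)$accept) { n_gate_rej <- n_gate_rej + 1L; next }
    s_new <- conf_distance(trial, goal, goal, mparams)
    if (!accept_move(s_cur, s_new, temperature)) next
    cur <- trial; s_cur <- s_new
    n_acc <- n_acc + 1L
    moves[[length(moves) + 1L]] <- list(dof = names(topo$dofs)[dof_i],
                                        delta = delta, repaired = FALSE)
    trace <- c(trace, s_cur)
    if (s_cur < best_s) { best <- cur; best_s <- s_cur; best_moves <- moves }
    if (best_s <= config$tau * d0) { success <- TRUE; break }
  }
  out <- list(success = success, best_normalized_distance = best_s / d0,
              best = best, moves = best_moves,
              path = replay_moves(topo, best_moves, eparams, keep = "all"),
              cycles = list(list(iterations = it, accepted = n_acc,
                                 gate_rejected = n_gate_rej,
                                 best_distance = best_s,
                                 best_normalized = best_s / d0)),
              e_start = e_start, config = config, trace = trace)
  class(out) <- "planner_result"
  out
}
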