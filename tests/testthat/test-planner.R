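zero_energy <- function(conf) 0

fresh_state <- function(config = planner_config(seed = 1),
                        energy_fn = zero_energy) {
  toy <- toy2()
  st <- pdst_state(toy$start, toy$goal, config = config,
                   energy_fn = energy_fn)
  st$e_start <- energy_fn(toy$start)
  st
}

test_that("selection follows priority / cell-volume with deterministic
           tie-breaks", {
  st <- fresh_state()
  # a single segment is always selected
  expect_equal(select_segment(st), 1L)
  # hand-crafted: equal priorities, cell volumes 8 vs 1
  st <- fresh_state()
  confpath:::new_segment(st, parent = 1L, parent_pos = 1L,
                         confs = st$segs[[1]]$confs,
                         moves = list(list(dof = "x", delta = 0,
                                           repaired = FALSE)),
                         proj = st$segs[[1]]$proj, priority = 1)
  st$pri[1:2] <- c(1, 1)
  st$cell_lo <- rbind(st$cell_lo, st$cell_lo)
  st$cell_hi <- rbind(st$cell_hi, st$cell_hi)
  st$ncell <- 2L
  st$cell_vol <- c(8, 1)
  st$seg_cell <- c(2L, 1L)   # segment 1 sits in the small cell
  expect_equal(select_segment(st), 2L)
  # the winner's priority doubles (+1)
  expect_equal(st$pri[2], 3)
  # tie on score: lowest id wins
  st$pri[1:2] <- c(1, 1); st$cell_vol <- c(1, 1)
  expect_equal(select_segment(st), 1L)
})

test_that("the priority recurrence selects every segment eventually", {
  st <- fresh_state()
  set.seed(2)
  for (k in 2:20)
    confpath:::new_segment(st, parent = 1L, parent_pos = 1L,
                           confs = st$segs[[1]]$confs,
                           moves = list(list(dof = "x", delta = 0,
                                             repaired = FALSE)),
                           proj = st$segs[[1]]$proj +
                             matrix(runif(st$d, -0.4, 0.4), 1),
                           priority = k)
  seen <- integer(0)
  for (it in 1:200) {
    sel <- select_segment(st, bias_on = FALSE)
    seen <- union(seen, sel)
    subdivide(st, st$seg_cell[sel])
  }
  expect_true(all(1:20 %in% seen))
})

test_that("subdivision halves cells at midpoints and keeps the partition
           exact", {
  st <- fresh_state()
  # normalize the root box to [0,2] x [0,2] for an exact midpoint check
  st$lo0 <- c(0, 0); st$hi0 <- c(2, 2)
  st$cell_lo <- matrix(c(0, 0), 1); st$cell_hi <- matrix(c(2, 2), 1)
  st$cell_depth <- 0L
  st$cell_vol <- 4
  st$segs[[1]]$proj <- matrix(c(0.5, 0.5), 1)
  st$seg_cell[1] <- 1L
  subdivide(st, 1L)
  expect_equal(st$ncell, 2L)
  expect_equal(unname(st$cell_hi[1, ]), c(1, 2))  # midpoint split on dim 1
  expect_equal(unname(st$cell_lo[2, ]), c(1, 0))
  expect_equal(unname(st$cell_vol), c(2, 2))
  # the segment is wholly in the left half and stays there
  expect_equal(st$seg_cell[1], 1L)

  # a segment spanning the new boundary is split into chained pieces
  proj <- rbind(c(0.2, 1.6), c(0.4, 1.6), c(0.6, 1.6), c(0.8, 1.6))
  confs <- rep(st$segs[[1]]$confs, 4)
  moves <- replicate(4, list(dof = "x", delta = 0, repaired = FALSE),
                     simplify = FALSE)
  sid <- confpath:::new_segment(st, parent = 1L, parent_pos = 1L,
                                confs = confs, moves = moves, proj = proj,
                                priority = 2)
  subdivide(st, st$seg_cell[sid])   # splits dim 2 of the left cell
  # every live segment's projection now lies in exactly one cell
  for (id in which(st$alive)) {
    cell <- st$seg_cell[id]
    pr <- st$segs[[id]]$proj
    inside <- pr >= matrix(st$cell_lo[cell, ], nrow(pr), st$d, byrow = TRUE) &
              pr <= matrix(st$cell_hi[cell, ], nrow(pr), st$d, byrow = TRUE)
    expect_true(all(inside))
  }
  # cells still tile the root box exactly
  expect_equal(sum(st$cell_vol), prod(st$hi0 - st$lo0))
})

test_that("split segments remain replayable through their parent chain", {
  toy <- toy2()
  cfg <- planner_config(iterations_per_cycle = 60, cycles = 3, tau = 0.2,
                        seed = 7)
  res <- run_pdst(toy$start, toy$goal, config = cfg)
  last <- res$path[[length(res$path)]]
  expect_lt(max(abs(last$xyz - res$best$xyz)), 1e-9)
})

test_that("propagation honours the energy gate", {
  toy <- toy2()
  # zero energy: the gate never fires, segments reach max_steps
  cfg <- planner_config(iterations_per_cycle = 5, cycles = 1, tau = 0.01,
                        max_steps = 7, seed = 3)
  st <- pdst_state(toy$start, toy$goal, config = cfg,
                   energy_fn = zero_energy)
  st$e_start <- 0
  set.seed(3)
  nid <- propagate(st, 1L, 1L)
  expect_false(is.na(nid))
  n_conf <- 0L; id <- nid
  repeat {
    n_conf <- n_conf + length(st$segs[[id]]$confs)
    nxt <- which(vapply(st$segs, function(s) isTRUE(s$parent == id), TRUE))
    nxt <- nxt[nxt > id]
    if (length(nxt) == 0) break
    id <- nxt[1]
  }
  expect_equal(n_conf, 7L)

  # strictly uphill energy: the very first step fails the gate
  uphill <- function(conf) {
    if (max(abs(conf$xyz - toy$start$xyz)) < 1e-12) 0 else 200
  }
  st2 <- pdst_state(toy$start, toy$goal, config = cfg, energy_fn = uphill)
  st2$e_start <- 0
  set.seed(3)
  expect_true(is.na(propagate(st2, 1L, 1L)))
})

test_that("accepted step counts match a one-dimensional walk oracle under a
           quadratic energy wall", {
  toy <- toy2()
  topo <- toy$topology
  ## quadratic wall in the displacement from the start: along any single-DOF
  ## walk it rises smoothly and crosses +50 kcal/mol mid-walk
  wall <- function(conf) 0.1 * sum((conf$xyz - toy$start$xyz)^2)
  cfg <- planner_config(iterations_per_cycle = 5, cycles = 1, tau = 0.01,
                        max_steps = 20, seed = 11)
  st <- pdst_state(toy$start, toy$goal, config = cfg, energy_fn = wall)
  st$e_start <- wall(toy$start)
  set.seed(11)
  ## replicate the planner's own draws to know which DOF it walks
  pos <- sample.int(1, 1)
  dof_i <- sample.int(length(topo$dofs), 1)
  sgn <- if (runif(1) < 0.5) 1 else -1
  d <- topo$dofs[[dof_i]]
  ## scalar oracle: walk the same DOF and count accepted steps
  expected <- 0L
  conf <- toy$start
  for (k in 1:20) {
    conf <- apply_dihedral(conf, names(topo$dofs)[dof_i],
                           sgn * cfg$delta_step)
    if (wall(conf) > st$e_start + 50) break
    expected <- expected + 1L
  }
  set.seed(11)
  nid <- propagate(st, 1L, 1L)
  got <- if (is.na(nid)) 0L else {
    n <- 0L; id <- nid
    repeat {
      n <- n + length(st$segs[[id]]$confs)
      nxt <- which(vapply(st$segs, function(s) isTRUE(s$parent == id), TRUE))
      nxt <- nxt[nxt > id]
      if (length(nxt) == 0) break
      id <- nxt[1]
    }
    n
  }
  expect_equal(got, expected)
  expect_gt(expected, 0L)   # the wall permits some but not all steps
  expect_lt(expected, 20L)
})

test_that("the full search is reproducible and bookkeeps cells correctly", {
  toy <- toy2()
  cfg <- planner_config(iterations_per_cycle = 40, cycles = 2, tau = 0.05,
                        seed = 17)
  r1 <- run_pdst(toy$start, toy$goal, config = cfg)
  r2 <- run_pdst(toy$start, toy$goal, config = cfg)
  expect_identical(r1$best$xyz, r2$best$xyz)
  expect_equal(r1$best_normalized_distance, r2$best_normalized_distance)
  st <- r1$state
  # one subdivision per selection: final cycle has selections + 1 cells
  last <- r1$cycles[[length(r1$cycles)]]
  expect_equal(st$ncell, last$selections + 1L)
  # cells tile the root box
  expect_equal(sum(st$cell_vol), prod(st$hi0 - st$lo0), tolerance = 1e-9)
  # every stored conformation passed the gate
  p <- energy_params()
  for (id in seq_along(st$segs))
    for (xyz in st$segs[[id]]$confs) {
      e <- compute_energy(conformation(toy$topology, xyz = xyz), p)$total
      expect_lte(e, r1$e_start + 50 + 1e-9)
    }
  expect_error(run_pdst(toy$start, toy$start, config = cfg), "coincide")
})

test_that("the toy hinge is solved quickly and the path is energy-sound", {
  toy <- toy2()
  cfg <- planner_config(iterations_per_cycle = 100, cycles = 20, tau = 0.2,
                        seed = 1)
  res <- run_pdst(toy$start, toy$goal, config = cfg)
  expect_true(res$success)
  expect_lte(res$best_normalized_distance, 0.2)
  expect_lte(sum(vapply(res$cycles, `[[`, 0L, "iterations")), 2000L)
  p <- energy_params()
  for (conf in res$path)
    expect_lte(compute_energy(conf, p)$total, res$e_start + 50 + 1e-9)
})
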