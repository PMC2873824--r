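## Synthetic articulated structures with known transitions. These are
## first-class generators: every search and analysis component can be
## exercised on them without any external structure files.

#' Build an ideal-geometry poly-alanine chain from backbone dihedrals
#'
#' Constructs a chain with standard bond lengths and angles, omega = 180
#' degrees, and the given per-residue phi/psi. Each residue carries N, CA,
#' C, O and an ideally placed CB.
#'
#' @param phi,psi numeric vectors (degrees), one value per residue. `phi[1]`
#'   and `psi[n]` are not realized (chain termini) but must be supplied.
#' @param aa residue three-letter codes (default all "ALA").
#' @return a `coarse_structure`.
#' @export
make_chain <- function(phi, psi, aa = rep("ALA", length(phi))) {
  n <- length(phi)
  stopifnot(length(psi) == n, length(aa) == n, n >= 2L)
  g <- .ideal
  phi <- deg2rad(phi); psi <- deg2rad(psi)
  N <- matrix(0, n, 3L); CA <- matrix(0, n, 3L); C <- matrix(0, n, 3L)
  # first residue in a canonical frame
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  ang <- deg2rad(g$ang_n_ca_c)
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n,
                              deg2rad(g$ang_ca_c_n), psi[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], g$b_n_ca,
                               deg2rad(g$ang_c_n_ca), deg2rad(g$omega))
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], g$b_ca_c,
                              deg2rad(g$ang_n_ca_c), phi[i + 1L])
  }
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    # carbonyl O antiperiplanar to the next N (psi - 180)
    psi_i <- if (i < n) psi[i] else deg2rad(-47)
    O <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o,
                    deg2rad(g$ang_ca_c_o), psi_i - pi)
    atoms <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O)
    if (toupper(aa[i]) != "GLY")
      atoms$CB <- ideal_cb(N[i, ], CA[i, ], C[i, ])
    coords[[i]] <- atoms
  }
  new_coarse_structure(aa, coords)
}

#' Build an ideal poly-alanine helix
#'
#' @param n_res number of residues (>= 4).
#' @param phi,psi helix dihedrals in degrees.
#' @return a `coarse_structure`.
#' @export
make_helix <- function(n_res, phi = -57, psi = -47) {
  if (n_res < 4L) stop("a helix fixture needs at least 4 residues")
  make_chain(rep(phi, n_res), rep(psi, n_res))
}

#' Build a toy transition: helices joined by loops, with known hinge moves
#'
#' Constructs `n_elements` ideal helices (12 residues each) joined by
#' 4-residue extended loops (phi = -120, psi = 130), then produces the goal
#' state by applying `hinge_deltas` (degrees) at the psi angle of the first
#' junction residue of each inter-element edge. Because the goal is built
#' inside the planner's own move space, a failure to find it isolates
#' search/metric defects rather than representational gaps. Should the goal
#' collapse sterically (interatomic distance < 1 Angstrom), the deltas are
#' jittered and the construction retried (error after 10 attempts).
#'
#' @param n_elements number of helices (>= 2).
#' @param hinge_deltas degrees, one per junction (length `n_elements - 1`).
#' @param seed integer seed for the jitter stream.
#' @param helix_len,loop_len fixture dimensions (residues).
#' @param mobile,window forwarded to [build_topology()].
#' @return list with `start` and `goal` conformations, the shared
#'   `topology`, `true_deltas` (named DOF offsets mapping start to goal)
#'   and the `seed` used.
#' @export
make_toy_transition <- function(n_elements = 2L, hinge_deltas = 30,
                                seed = 1L, helix_len = 12L, loop_len = 4L,
                                mobile = "all", window = 2L) {
  stopifnot(n_elements >= 2L, length(hinge_deltas) == n_elements - 1L)
  n_j <- n_elements - 1L
  phi <- c(); psi <- c(); kind <- c()
  for (e in seq_len(n_elements)) {
    phi <- c(phi, rep(-57, helix_len)); psi <- c(psi, rep(-47, helix_len))
    kind <- c(kind, rep("helix", helix_len))
    if (e < n_elements) {
      phi <- c(phi, rep(-120, loop_len)); psi <- c(psi, rep(130, loop_len))
      kind <- c(kind, rep("coil", loop_len))
    }
  }
  start_struct <- make_chain(phi, psi)
  sse <- runs_to_ranges(kind)

  rng <- local({ set.seed(seed); function(n) stats::runif(n) })
  deltas <- hinge_deltas
  for (attempt in seq_len(10L)) {
    topo0 <- build_topology(start_struct, start_struct, sse = sse,
                            mobile = mobile, window = window)
    # the psi DOF of the first junction residue of each tree edge
    hinge_names <- character(n_j)
    non_root <- which(!is.na(topo0$tree$parent))
    stopifnot(length(non_root) == n_j)
    for (k in seq_len(n_j)) {
      child <- non_root[k]
      r1 <- min(topo0$tree$junction[child, ])
      hinge_names[k] <- sprintf("psi_%d.e%d", r1, child)
    }
    stopifnot(all(hinge_names %in% names(topo0$dofs)))
    conf <- start_conformation(topo0)
    for (k in seq_len(n_j))
      conf <- apply_dihedral(conf, hinge_names[k], deg2rad(deltas[k]))
    dmin <- min(stats::dist(conf$xyz))
    if (dmin >= 1.0) {
      goal_struct <- start_struct
      goal_struct$xyz <- conf$xyz
      topo <- build_topology(start_struct, goal_struct, sse = sse,
                             mobile = mobile, window = window)
      true_deltas <- numeric(length(topo$dofs))
      names(true_deltas) <- names(topo$dofs)
      true_deltas[hinge_names] <- deg2rad(deltas)
      return(list(start = start_conformation(topo),
                  goal = goal_conformation(topo),
                  topology = topo, true_deltas = true_deltas,
                  hinge_dofs = hinge_names, seed = seed))
    }
    deltas <- hinge_deltas + (rng(n_j) - 0.5) * 10
  }
  stop("could not build a clash-free goal after 10 attempts")
}
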