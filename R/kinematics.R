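## Forward kinematics: conformations as DOF offsets over a fixed topology,
## dihedral rotations propagating rigid-body motion down the spanning tree.

#' Create a conformation over a pathway topology
#'
#' A conformation couples a coordinate set with the topology it articulates
#' and the vector of phi/psi offsets (radians, relative to the start
#' structure) that produced it.
#'
#' @param topology a `pathway_topology`.
#' @param xyz coordinate matrix (defaults to the start structure's).
#' @param dof_values named offset vector (defaults to all zero).
#' @return object of class `conformation`.
#' @export
conformation <- function(topology, xyz = topology$structure$xyz,
                         dof_values = NULL) {
  stopifnot(inherits(topology, "pathway_topology"))
  if (is.null(dof_values)) {
    dof_values <- numeric(length(topology$dofs))
    names(dof_values) <- names(topology$dofs)
  }
  stopifnot(nrow(xyz) == nrow(topology$structure$xyz))
  out <- list(topology = topology, xyz = xyz, dof_values = dof_values)
  class(out) <- "conformation"
  out
}

#' @rdname conformation
#' @export
start_conformation <- function(topology) conformation(topology)

#' @rdname conformation
#' @export
goal_conformation <- function(topology)
  conformation(topology, xyz = topology$goal_structure$xyz)

#' @export
print.conformation <- function(x, ...) {
  nz <- sum(x$dof_values != 0)
  cat(sprintf("conformation: %d atoms, %d/%d non-zero DOF offsets\n",
              nrow(x$xyz), nz, length(x$dof_values)))
  invisible(x)
}

#' Rotate one degree of freedom
#'
#' Rotates all atoms distal to the DOF's bond (N-CA axis for phi, CA-C axis
#' for psi; the distal side fixed by the spanning-tree direction) by `delta`
#' radians about the bond axis. The measured dihedral at that residue
#' changes by exactly `+delta`; proximal atoms are untouched, and all
#' intra-rigid-element distances are preserved.
#'
#' @param conf a `conformation`.
#' @param dof a DOF name, index into the topology's DOF list, or DOF record.
#' @param delta rotation in radians.
#' @return the rotated `conformation`.
#' @export
apply_dihedral <- function(conf, dof, delta) {
  if (!is.finite(delta)) stop("delta must be finite")
  d <- resolve_dof(conf$topology, dof)
  if (delta == 0) return(conf)
  p1 <- conf$xyz[d$axis[1L], ]
  p2 <- conf$xyz[d$axis[2L], ]
  theta <- if (d$direction == "down") -delta else delta
  conf$xyz[d$moved_rows, ] <-
    rotate_about_axis(conf$xyz[d$moved_rows, , drop = FALSE], p1, p2 - p1,
                      theta)
  conf$dof_values[d$name] <- conf$dof_values[d$name] + delta
  conf
}

resolve_dof <- function(topology, dof) {
  if (is.list(dof)) return(dof)
  d <- topology$dofs[[dof]]
  if (is.null(d)) stop("unknown DOF: ", dof)
  d
}

#' Measure a backbone dihedral of a conformation
#'
#' Standard signed dihedral in (-pi, pi]: phi(i) = C(i-1)-N(i)-CA(i)-C(i),
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#'
#' @param conf a `conformation` (or `coarse_structure`).
#' @param residue 0-based residue index.
#' @param kind "phi" or "psi".
#' @return angle in radians; `NA` at a terminus or chain break.
#' @export
measure_dihedral <- function(conf, residue, kind = c("phi", "psi")) {
  kind <- match.arg(kind)
  s <- if (inherits(conf, "conformation")) conf$topology$structure else conf
  xyz <- if (inherits(conf, "conformation")) conf$xyz else conf$xyz
  n <- n_residues(s)
  if (kind == "phi") {
    if (residue == 0L || (residue - 1L) %in% s$breaks) return(NA_real_)
    p <- list(atom_xyz(s, residue - 1L, "C", xyz),
              atom_xyz(s, residue, "N", xyz),
              atom_xyz(s, residue, "CA", xyz),
              atom_xyz(s, residue, "C", xyz))
  } else {
    if (residue == n - 1L || residue %in% s$breaks) return(NA_real_)
    p <- list(atom_xyz(s, residue, "N", xyz),
              atom_xyz(s, residue, "CA", xyz),
              atom_xyz(s, residue, "C", xyz),
              atom_xyz(s, residue + 1L, "N", xyz))
  }
  if (any(vapply(p, is.null, TRUE))) return(NA_real_)
  dihedral(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
}

#' Replay a sequence of DOF offsets from the start state
#'
#' Applies the given offsets (in DOF-list order) to the topology's start
#' conformation, reproducing any conformation from its `dof_values`.
#'
#' @param topology a `pathway_topology`.
#' @param dof_values named offset vector.
#' @return the resulting `conformation`.
#' @export
replay_dofs <- function(topology, dof_values) {
  conf <- start_conformation(topology)
  for (nm in names(topology$dofs)) {
    v <- dof_values[[nm]]
    if (!is.null(v) && is.finite(v) && v != 0)
      conf <- apply_dihedral(conf, nm, v)
  }
  conf
}
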