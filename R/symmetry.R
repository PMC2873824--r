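## Cyclic (Cn) symmetric complexes: a single monomer is replicated by exact
## rotational transforms, and metric/energy cross terms are restricted to
## adjacent monomers (distant subunits of a ring do not interact). Intra-unit
## terms are computed once and reused for every unit.

#' Define a cyclic symmetry group
#'
#' @param n group order (>= 2); e.g. 7 for a single chaperonin ring.
#' @param axis rotation axis direction.
#' @param point a point on the axis.
#' @return list of class `symmetry_group` with `n`, `axis`, `point` and
#'   `transforms` (list of 3x3 rotation matrices; k-th rotates by
#'   2*pi*(k-1)/n, the first being the identity).
#' @export
symmetry_group <- function(n, axis = c(0, 0, 1), point = c(0, 0, 0)) {
  if (n < 2L) stop("a symmetric complex needs order >= 2")
  axis <- unit(axis)
  transforms <- lapply(seq_len(n) - 1L, function(k)
    rotation_matrix(axis, 2 * pi * k / n))
  out <- list(n = as.integer(n), axis = axis, point = point,
              transforms = transforms)
  class(out) <- "symmetry_group"
  out
}

sym_apply <- function(group, k, xyz) {
  ## k is 0-based unit index
  R <- group$transforms[[(k %% group$n) + 1L]]
  sweep(sweep(xyz, 2L, group$point) %*% t(R), 2L, group$point, `+`)
}

#' Replicate a monomer into an exactly symmetric complex
#'
#' @param monomer a `conformation` or coordinate matrix.
#' @param group a `symmetry_group`.
#' @return list of `n` coordinate matrices; copy k+1 is the monomer rotated
#'   by 2*pi*k/n about the group axis.
#' @export
build_complex <- function(monomer, group) {
  xyz <- if (inherits(monomer, "conformation")) monomer$xyz else monomer
  lapply(seq_len(group$n) - 1L, function(k) sym_apply(group, k, xyz))
}

## Nonbonded interaction energy between two rigid copies of the monomer:
## soft vdW over all cross pairs, backbone hydrogen bonds (both donor
## directions), the water-shell term, and the burial contributions of
## cross-unit C-beta contacts (both endpoints). No bonded terms cross units.
cross_unit_energy <- function(xyzA, xyzB, s, params) {
  cls <- .lj_class[s$atom_name]
  rh <- params$lj_rmin_half[cls]
  ep <- params$lj_eps[cls]
  M <- nrow(xyzA)
  ## all-pairs distances between units
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), `+`) -
        2 * xyzA %*% t(xyzB)
  d <- sqrt(pmax(d2, 0))
  sigma <- outer(rh, rh, `+`) / 2^(1 / 6)
  eps <- sqrt(outer(ep, ep))
  xcap <- (1 + sqrt(1 + params$vdw_cap / eps)) / 2
  rcap <- sigma / xcap^(1 / 6)
  x <- (sigma / d)^6
  e_lj <- 4 * eps * (x^2 - x)
  e_lj[d < rcap] <- params$vdw_cap
  vdw <- sum(e_lj)

  n_rows <- atom_rows(s, "N"); o_rows <- atom_rows(s, "O")
  hb <- -params$hb_epsilon *
    (sum(hb_switch_fn(as.vector(d[n_rows, o_rows]), params$hb_range,
                      params$hb_switch)) +
     sum(hb_switch_fn(as.vector(d[o_rows, n_rows]), params$hb_range,
                      params$hb_switch)))

  cb_rows <- atom_rows(s, "CB")
  cb_res <- s$atom_res[cb_rows] + 1L
  kd <- .kd[s$aa[cb_res]]
  kd[is.na(kd)] <- 0
  dcb <- d[cb_rows, cb_rows, drop = FALSE]
  contact <- dcb <= params$burial_radius
  bw <- -params$burial_weight * kd
  burial <- sum(outer(bw, bw, `+`)[contact])
  shell <- dcb >= params$water_shell[1L] & dcb <= params$water_shell[2L]
  ww <- params$water_eps * outer(kd / 4.5, kd / 4.5)
  water <- sum(ww[shell])

  vdw + hb + burial + water
}

#' Symmetry-aware metric and energy contributions
#'
#' Exploits exact Cn symmetry: intra-unit quantities are computed once on
#' the monomer and reused for all `n` units, and cross terms are taken only
#' between adjacent units (each adjacent pair contributes identically, so
#' one representative pair is evaluated).
#'
#' In `energy` mode, returns the total complex energy
#' `n * (E_intra + E_cross(0, 1))`, with the per-part breakdown. In
#' `metric` mode, returns the feature vector of the unit-0 mobile elements
#' where each score gains cross terms against all elements of the two
#' adjacent units.
#'
#' @param conf monomer `conformation`.
#' @param group a `symmetry_group`.
#' @param mode "energy" or "metric".
#' @param goal goal monomer `conformation` (metric mode).
#' @param params an `energy_params` (energy mode) or `metric_params`
#'   (metric mode).
#' @return see above.
#' @export
symmetric_terms <- function(conf, group, mode = c("energy", "metric"),
                            goal = NULL, params = NULL) {
  mode <- match.arg(mode)
  if (mode == "energy") {
    if (is.null(params)) params <- energy_params()
    s <- conf$topology$structure
    intra <- compute_energy(conf, params)$total
    units <- build_complex(conf, group)
    cross <- cross_unit_energy(units[[1L]], units[[2L]], s, params)
    list(intra = intra, cross_adjacent = cross,
         total = group$n * (intra + cross))
  } else {
    if (is.null(params)) params <- metric_params()
    if (is.null(goal)) stop("metric mode needs the goal conformation")
    symmetric_feature_vector(conf, goal, group, params)
  }
}

#' Total energy of the symmetric complex
#'
#' @inheritParams symmetric_terms
#' @return scalar kcal/mol.
#' @export
complex_energy <- function(conf, group, params = energy_params())
  symmetric_terms(conf, group, "energy", params = params)$total

## Per-element axes and centers of mass of the monomer, transformed to unit k.
unit_element_geometry <- function(conf, group, k) {
  topo <- conf$topology
  ne <- length(topo$elements)
  R <- group$transforms[[(k %% group$n) + 1L]]
  axes <- vector("list", ne); coms <- vector("list", ne)
  for (e in seq_len(ne)) {
    ax <- element_axis(conf, e)
    com <- element_com(conf, e)
    a2 <- as.vector(R %*% ax)
    attr(a2, "oriented") <- attr(ax, "oriented")
    axes[[e]] <- a2
    coms[[e]] <- as.vector(R %*% (com - group$point)) + group$point
  }
  list(axes = axes, coms = coms)
}

pair_geom_from <- function(ax_i, com_i, ax_j, com_j) {
  dt <- max(-1, min(1, sum(ax_i * ax_j)))
  alpha <- if (attr(ax_i, "oriented") && attr(ax_j, "oriented")) acos(dt)
           else acos(abs(dt))
  list(alpha = alpha, dist = vnorm(com_i - com_j))
}

#' Feature vector of a symmetric complex
#'
#' Scores of the unit-0 mobile elements: the monomer's intra-unit terms
#' plus cross terms against every element of the two adjacent units, all
#' measured against the same geometry in the goal complex.
#'
#' @param conf,goal monomer conformations (shared topology).
#' @param group a `symmetry_group`.
#' @param params a `metric_params`.
#' @return numeric vector over the mobile set.
#' @export
symmetric_feature_vector <- function(conf, goal, group,
                                     params = metric_params()) {
  topo <- conf$topology
  mobile <- topo$mobile
  base <- feature_vector(conf, goal, params)
  g0c <- unit_element_geometry(conf, group, 0L)
  g0g <- unit_element_geometry(goal, group, 0L)
  for (k in c(1L, group$n - 1L)) {
    gkc <- unit_element_geometry(conf, group, k)
    gkg <- unit_element_geometry(goal, group, k)
    for (a in seq_along(mobile)) {
      i <- mobile[a]
      for (j in seq_along(topo$elements)) {
        pc <- pair_geom_from(g0c$axes[[i]], g0c$coms[[i]],
                             gkc$axes[[j]], gkc$coms[[j]])
        pg <- pair_geom_from(g0g$axes[[i]], g0g$coms[[i]],
                             gkg$axes[[j]], gkg$coms[[j]])
        da <- abs(pc$alpha - pg$alpha)
        dd <- abs(pc$dist - pg$dist)
        if (params$form == "squared") { da <- da^2; dd <- dd^2 }
        base[a] <- base[a] + params$w_angle * da + params$w_dist * dd
      }
    }
  }
  base
}
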