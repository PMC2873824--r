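## Coarse-grained potential over the backbone + C-beta representation:
## capped soft Lennard-Jones, backbone hydrogen bonds, a C-beta burial term,
## a water-shell pairwise solvation term, and harmonic bond/angle terms
## (AMBER-style constants) over the flexible loop windows. Plus the
## high-energy gate and the short steepest-descent repair.

## Kyte-Doolittle hydropathy, used to weight burial and water-shell terms.
.kd <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
         GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
         LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
         SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

## Atom class per retained atom name (AMBER-style nonbonded classes).
.lj_class <- c(N = "N", CA = "CT", C = "C", O = "O", CB = "CT")
.lj_rmin_half <- c(N = 1.824, CT = 1.908, C = 1.908, O = 1.6612)
.lj_eps <- c(N = 0.17, CT = 0.1094, C = 0.086, O = 0.21)

#' Energy-function parameters
#'
#' All energies in kcal/mol, lengths in Angstrom. `vdw_cap` bounds each
#' pairwise repulsion so clashed conformations stay finite (the 12-6 curve
#' is continued flat below its cap-crossing radius). The hydrogen-bond term
#' rewards backbone N...O pairs inside `hb_range`, switching smoothly to
#' zero over `hb_switch` outside it. Burial counts C-beta contacts within
#' `burial_radius`, weighted per residue type by `burial_scale`
#' (hydropathy-scaled; hydrophobic burial is favourable). The water term
#' penalizes hydrophobic C-beta pairs held at water-separated distances
#' (`water_shell`). Bond and angle constants follow the AMBER ff03 backbone
#' values shipped with the package.
#'
#' @param vdw_cap cap on each pairwise repulsion (kcal/mol).
#' @param hb_epsilon hydrogen-bond well depth (kcal/mol).
#' @param hb_range N-O distance window (Angstrom).
#' @param hb_switch switching width outside the window (Angstrom).
#' @param burial_radius C-beta contact radius (Angstrom).
#' @param burial_weight kcal/mol per contact per hydropathy unit.
#' @param water_shell solvent-separated C-beta distance window (Angstrom).
#' @param water_eps scale of the pairwise water term (kcal/mol).
#' @param exclusion minimum residue separation for nonbonded pairs.
#' @param lj_rmin_half,lj_eps named per-class Lennard-Jones parameters.
#' @param ff path to the bonded-parameter table (CSV).
#' @return list of class `energy_params`.
#' @export
energy_params <- function(vdw_cap = 10, hb_epsilon = 2.0,
                          hb_range = c(2.6, 3.4), hb_switch = 0.4,
                          burial_radius = 8.0, burial_weight = 0.02,
                          water_shell = c(6.5, 9.5), water_eps = 0.05,
                          exclusion = 3L,
                          lj_rmin_half = .lj_rmin_half, lj_eps = .lj_eps,
                          ff = NULL) {
  if (is.null(ff))
    ff <- system.file("extdata", "ff03_backbone.csv", package = "confpath")
  if (!nzchar(ff) || !file.exists(ff)) ff <- "inst/extdata/ff03_backbone.csv"
  tab <- utils::read.csv(ff, stringsAsFactors = FALSE)
  stopifnot(hb_range[1L] < hb_range[2L], water_shell[1L] < water_shell[2L],
            hb_range[2L] <= water_shell[1L])
  out <- list(vdw_cap = vdw_cap, hb_epsilon = hb_epsilon,
              hb_range = hb_range, hb_switch = hb_switch,
              burial_radius = burial_radius, burial_weight = burial_weight,
              water_shell = water_shell, water_eps = water_eps,
              exclusion = as.integer(exclusion),
              lj_rmin_half = lj_rmin_half, lj_eps = lj_eps,
              bonds = tab[tab$type == "bond", ],
              angles = tab[tab$type == "angle", ])
  class(out) <- "energy_params"
  out
}

## ---- precomputed per-topology tables ------------------------------------

energy_tables <- function(topo, params) {
  hit <- topo$cache[["energy_tables"]]
  if (!is.null(hit) && identical(hit$params, params)) return(hit$tables)
  s <- topo$structure
  n <- n_residues(s)
  M <- nrow(s$xyz)

  ## nonbonded pairs with sequence separation >= exclusion
  pr <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
  sep <- abs(s$atom_res[pr[, 1L]] - s$atom_res[pr[, 2L]])
  keep <- sep >= params$exclusion
  nb_i <- pr[keep, 1L]; nb_j <- pr[keep, 2L]
  cls <- .lj_class[s$atom_name]
  rh <- params$lj_rmin_half
  ep <- params$lj_eps
  rmin <- rh[cls[nb_i]] + rh[cls[nb_j]]
  sigma <- rmin / 2^(1 / 6)
  eps <- sqrt(ep[cls[nb_i]] * ep[cls[nb_j]])
  ## cap-crossing radius: 4e(x^2 - x) = cap with x = (sigma/r)^6
  xcap <- (1 + sqrt(1 + params$vdw_cap / eps)) / 2
  rcap <- sigma / xcap^(1 / 6)

  ## backbone hydrogen-bond pairs N(i)...O(j), |i - j| >= 3, both orders
  n_rows <- s$idx[, "N"]; o_rows <- s$idx[, "O"]
  hb_i <- integer(0); hb_j <- integer(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 3L) next
    if (is.na(n_rows[i]) || is.na(o_rows[j])) next
    hb_i <- c(hb_i, n_rows[i]); hb_j <- c(hb_j, o_rows[j])
  }

  ## C-beta rows and residue-type weights
  cb_rows <- s$idx[, "CB"]
  cb_res <- which(!is.na(cb_rows))
  cb_rows <- cb_rows[cb_res]
  kd <- .kd[s$aa[cb_res]]
  kd[is.na(kd)] <- 0
  burial_w <- -params$burial_weight * kd
  nb_cb <- which(upper.tri(matrix(0, length(cb_rows), length(cb_rows))),
                 arr.ind = TRUE)
  water_w <- params$water_eps * (kd[nb_cb[, 1L]] / 4.5) *
             (kd[nb_cb[, 2L]] / 4.5)

  ## bonded terms over the loop windows only (rigid elements never deform
  ## under dihedral moves, so their bonded terms are constant by design)
  win <- sort(unique(vapply(topo$dofs, `[[`, 0L, "residue")))
  bt <- bonded_tables(s, params, win)

  tables <- list(nb_i = nb_i, nb_j = nb_j, sigma = sigma, eps = eps,
                 rcap = rcap, hb_i = hb_i, hb_j = hb_j,
                 cb_rows = cb_rows, cb_pair = nb_cb, burial_w = burial_w,
                 water_w = water_w, bonds = bt$bonds, angles = bt$angles,
                 window_res = win)
  assign("energy_tables", list(params = params, tables = tables),
         envir = topo$cache)
  tables
}

## bonds: matrix (i, j, k, r0); angles: matrix (a, b, c, k, theta0[rad]);
## restricted to terms touching the window residues.
bonded_tables <- function(s, params, win) {
  n <- n_residues(s)
  bdef <- params$bonds; adef <- params$angles
  bk <- function(a1, a2) {
    r <- bdef[bdef$a1 == a1 & bdef$a2 == a2, ]
    c(r$k[1L], r$ref[1L])
  }
  ak <- function(a1, a2, a3) {
    r <- adef[adef$a1 == a1 & adef$a2 == a2 & adef$a3 == a3, ]
    c(r$k[1L], deg2rad(r$ref[1L]))
  }
  row_of <- function(i, nm) if (i >= 0L && i < n) s$idx[i + 1L, nm]
                            else NA_integer_
  bonds <- NULL; angles <- NULL
  in_win <- function(res) any(res %in% win)
  for (i in (seq_len(n) - 1L)) {
    nxt <- if (!(i %in% s$breaks) && i < n - 1L) i + 1L else NA_integer_
    bspec <- list(list(c("N", i), c("CA", i), bk("N", "CA")),
                  list(c("CA", i), c("C", i), bk("CA", "C")),
                  list(c("C", i), c("O", i), bk("C", "O")),
                  list(c("CA", i), c("CB", i), bk("CA", "CB")))
    if (!is.na(nxt))
      bspec <- c(bspec, list(list(c("C", i), c("N", nxt), bk("C", "N"))))
    for (b in bspec) {
      ri <- as.integer(b[[1L]][2L]); rj <- as.integer(b[[2L]][2L])
      if (!in_win(c(ri, rj))) next
      r1 <- row_of(ri, b[[1L]][1L]); r2 <- row_of(rj, b[[2L]][1L])
      if (is.na(r1) || is.na(r2)) next
      bonds <- rbind(bonds, c(r1, r2, b[[3L]]))
    }
    aspec <- list(list(c("N", i), c("CA", i), c("C", i), ak("N", "CA", "C")),
                  list(c("N", i), c("CA", i), c("CB", i),
                       ak("N", "CA", "CB")),
                  list(c("CB", i), c("CA", i), c("C", i),
                       ak("CB", "CA", "C")),
                  list(c("CA", i), c("C", i), c("O", i), ak("CA", "C", "O")))
    if (!is.na(nxt))
      aspec <- c(aspec,
                 list(list(c("CA", i), c("C", i), c("N", nxt),
                           ak("CA", "C", "N")),
                      list(c("O", i), c("C", i), c("N", nxt),
                           ak("O", "C", "N")),
                      list(c("C", i), c("N", nxt), c("CA", nxt),
                           ak("C", "N", "CA"))))
    for (a in aspec) {
      res3 <- as.integer(c(a[[1L]][2L], a[[2L]][2L], a[[3L]][2L]))
      if (!in_win(res3)) next
      r1 <- row_of(res3[1L], a[[1L]][1L])
      r2 <- row_of(res3[2L], a[[2L]][1L])
      r3 <- row_of(res3[3L], a[[3L]][1L])
      if (anyNA(c(r1, r2, r3))) next
      angles <- rbind(angles, c(r1, r2, r3, a[[4L]]))
    }
  }
  list(bonds = bonds, angles = angles)
}

## ---- term evaluation -----------------------------------------------------

pair_dist <- function(xyz, i, j) sqrt(rowSums((xyz[i, , drop = FALSE] -
                                               xyz[j, , drop = FALSE])^2))

lj_energy <- function(d, sigma, eps, rcap, cap) {
  x <- (sigma / d)^6
  e <- 4 * eps * (x^2 - x)
  e[d < rcap] <- cap
  e
}

hb_switch_fn <- function(d, range, width) {
  s <- numeric(length(d))
  inside <- d >= range[1L] & d <= range[2L]
  s[inside] <- 1
  lo <- d < range[1L] & d > range[1L] - width
  s[lo] <- 0.5 * (1 - cos(pi * (d[lo] - (range[1L] - width)) / width))
  hi <- d > range[2L] & d < range[2L] + width
  s[hi] <- 0.5 * (1 + cos(pi * (d[hi] - range[2L]) / width))
  s
}

#' Coarse-grained energy of a conformation
#'
#' Evaluates the six-term potential and returns the per-term breakdown.
#' The total is always finite: pairwise repulsions are capped.
#'
#' @param conf a `conformation`.
#' @param params an `energy_params`.
#' @return list of class `energy_breakdown` with components `soft_vdw`,
#'   `hbond`, `burial`, `water`, `bond`, `angle`, `total` (kcal/mol).
#' @export
compute_energy <- function(conf, params = energy_params()) {
  stopifnot(all(is.finite(conf$xyz)))
  tb <- energy_tables(conf$topology, params)
  xyz <- conf$xyz

  d <- pair_dist(xyz, tb$nb_i, tb$nb_j)
  soft_vdw <- sum(lj_energy(d, tb$sigma, tb$eps, tb$rcap, params$vdw_cap))

  hbond <- if (length(tb$hb_i))
    -params$hb_epsilon * sum(hb_switch_fn(pair_dist(xyz, tb$hb_i, tb$hb_j),
                                          params$hb_range, params$hb_switch))
  else 0

  burial <- 0; water <- 0
  if (length(tb$cb_rows) >= 2L) {
    dc <- pair_dist(xyz, tb$cb_rows[tb$cb_pair[, 1L]],
                    tb$cb_rows[tb$cb_pair[, 2L]])
    contact <- dc <= params$burial_radius
    counts <- tabulate(c(tb$cb_pair[contact, 1L], tb$cb_pair[contact, 2L]),
                       nbins = length(tb$cb_rows))
    burial <- sum(tb$burial_w * counts)
    shell <- dc >= params$water_shell[1L] & dc <= params$water_shell[2L]
    water <- sum(tb$water_w[shell])
  }

  bond <- if (!is.null(tb$bonds)) {
    db <- pair_dist(xyz, tb$bonds[, 1L], tb$bonds[, 2L])
    sum(tb$bonds[, 3L] * (db - tb$bonds[, 4L])^2)
  } else 0
  angle <- if (!is.null(tb$angles)) {
    th <- vapply(seq_len(nrow(tb$angles)), function(r)
      bond_angle(xyz[tb$angles[r, 1L], ], xyz[tb$angles[r, 2L], ],
                 xyz[tb$angles[r, 3L], ]), 0)
    sum(tb$angles[, 4L] * (th - tb$angles[, 5L])^2)
  } else 0

  out <- list(soft_vdw = soft_vdw, hbond = hbond, burial = burial,
              water = water, bond = bond, angle = angle,
              total = soft_vdw + hbond + burial + water + bond + angle)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("energy (kcal/mol): total %.3f  [soft_vdw %.3f, ",
                     "hbond %.3f, burial %.3f, water %.3f, bond %.3f, ",
                     "angle %.3f]\n"),
              x$total, x$soft_vdw, x$hbond, x$burial, x$water, x$bond,
              x$angle))
  invisible(x)
}

#' High-energy gate
#'
#' A conformation is rejected as high-energy when it lies more than
#' `reject_above` (50) kcal/mol above the starting energy; at or beyond
#' `repair_at` (100) kcal/mol above, a short steepest-descent repair is
#' additionally requested before re-gating.
#'
#' @param e_current,e_start energies (kcal/mol).
#' @param reject_above,repair_at gate offsets (kcal/mol).
#' @return list with logicals `accept` and `repair`.
#' @export
energy_gate <- function(e_current, e_start, reject_above = 50,
                        repair_at = 100) {
  stopifnot(is.finite(e_current), is.finite(e_start))
  list(accept = e_current <= e_start + reject_above,
       repair = e_current >= e_start + repair_at)
}

## ---- steepest-descent repair --------------------------------------------

## Gradient of bond + angle + soft_vdw restricted to `rows`; returns an
## (length(rows) x 3) matrix.
repair_gradient <- function(xyz, tb, params, rows) {
  g <- matrix(0, nrow(xyz), 3L)
  inset <- logical(nrow(xyz)); inset[rows] <- TRUE

  sel <- which(inset[tb$nb_i] | inset[tb$nb_j])
  if (length(sel)) {
    i <- tb$nb_i[sel]; j <- tb$nb_j[sel]
    dv <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    x <- (tb$sigma[sel] / d)^6
    dEdr <- 4 * tb$eps[sel] * (-12 * x^2 + 6 * x) / d
    dEdr[d < tb$rcap[sel]] <- 0           # flat cap region
    gv <- dv * (dEdr / d)
    for (k in seq_along(sel)) {
      if (inset[i[k]]) g[i[k], ] <- g[i[k], ] + gv[k, ]
      if (inset[j[k]]) g[j[k], ] <- g[j[k], ] - gv[k, ]
    }
  }

  if (!is.null(tb$bonds)) {
    sel <- which(inset[tb$bonds[, 1L]] | inset[tb$bonds[, 2L]])
    for (r in sel) {
      i <- tb$bonds[r, 1L]; j <- tb$bonds[r, 2L]
      dv <- xyz[i, ] - xyz[j, ]
      d <- vnorm(dv)
      gv <- 2 * tb$bonds[r, 3L] * (d - tb$bonds[r, 4L]) * dv / d
      if (inset[i]) g[i, ] <- g[i, ] + gv
      if (inset[j]) g[j, ] <- g[j, ] - gv
    }
  }

  if (!is.null(tb$angles)) {
    sel <- which(inset[tb$angles[, 1L]] | inset[tb$angles[, 2L]] |
                 inset[tb$angles[, 3L]])
    for (r in sel) {
      a <- tb$angles[r, 1L]; b <- tb$angles[r, 2L]; c3 <- tb$angles[r, 3L]
      u <- xyz[a, ] - xyz[b, ]; v <- xyz[c3, ] - xyz[b, ]
      ru <- vnorm(u); rv <- vnorm(v)
      uh <- u / ru; vh <- v / rv
      ct <- max(-1, min(1, sum(uh * vh)))
      st <- sqrt(max(1e-12, 1 - ct^2))
      th <- acos(ct)
      pref <- 2 * tb$angles[r, 4L] * (th - tb$angles[r, 5L])
      ga <- pref * (ct * uh - vh) / (ru * st)
      gc <- pref * (ct * vh - uh) / (rv * st)
      gb <- -ga - gc
      if (inset[a]) g[a, ] <- g[a, ] + ga
      if (inset[b]) g[b, ] <- g[b, ] + gb
      if (inset[c3]) g[c3, ] <- g[c3, ] + gc
    }
  }
  g[rows, , drop = FALSE]
}

repair_objective <- function(xyz, tb, params) {
  d <- pair_dist(xyz, tb$nb_i, tb$nb_j)
  e <- sum(lj_energy(d, tb$sigma, tb$eps, tb$rcap, params$vdw_cap))
  if (!is.null(tb$bonds)) {
    db <- pair_dist(xyz, tb$bonds[, 1L], tb$bonds[, 2L])
    e <- e + sum(tb$bonds[, 3L] * (db - tb$bonds[, 4L])^2)
  }
  if (!is.null(tb$angles)) {
    th <- vapply(seq_len(nrow(tb$angles)), function(r)
      bond_angle(xyz[tb$angles[r, 1L], ], xyz[tb$angles[r, 2L], ],
                 xyz[tb$angles[r, 3L], ]), 0)
    e <- e + sum(tb$angles[, 4L] * (th - tb$angles[, 5L])^2)
  }
  e
}

#' Short steepest-descent repair of a high-energy conformation
#'
#' Displaces the atoms of the manipulated rigid elements (plus their
#' junction windows) along the negative gradient of the bond, angle and
#' soft van der Waals terms, with a backtracking step size starting at
#' `step0` (Angstrom per kcal/mol/Angstrom of gradient). The objective is
#' non-increasing across accepted steps; all other atoms are untouched.
#'
#' @param conf a `conformation`.
#' @param moved_elements element ids manipulated by the move under repair.
#' @param params an `energy_params`.
#' @param steps maximum descent steps (default 20).
#' @param step0 initial step scale.
#' @return the repaired `conformation`.
#' @export
local_minimize <- function(conf, moved_elements, params = energy_params(),
                           steps = 20L, step0 = 0.01) {
  stopifnot(steps >= 1L)
  topo <- conf$topology
  tb <- energy_tables(topo, params)
  res <- unique(unlist(topo$elements[moved_elements]))
  for (d in topo$dofs)
    if (any(d$distal %in% moved_elements)) res <- union(res, d$residue)
  rows <- residue_rows(topo$structure, res)
  xyz <- conf$xyz
  e_cur <- repair_objective(xyz, tb, params)
  trace <- e_cur
  for (it in seq_len(steps)) {
    g <- repair_gradient(xyz, tb, params, rows)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    alpha <- step0
    accepted <- FALSE
    for (h in 1:12) {
      trial <- xyz
      trial[rows, ] <- xyz[rows, , drop = FALSE] - alpha * g
      e_try <- repair_objective(trial, tb, params)
      if (e_try <= e_cur) {
        xyz <- trial; e_cur <- e_try; accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    trace <- c(trace, e_cur)
  }
  conf$xyz <- xyz
  attr(conf, "objective_trace") <- trace
  conf
}
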