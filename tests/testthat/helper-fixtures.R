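# Shared fixtures and independent oracles. Fixtures are generated in code;
# expensive ones are memoized for the duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

toy2 <- function() memo("toy2", make_toy_transition(2L, 30, seed = 1L))

## Three helices (small-big-small) with both loops moved in the goal, so the
## central element is the root and the two subtrees are disjoint (one "up",
## one "down" DOF family).
toy3_mid <- function() memo("toy3_mid", {
  seg_phi <- c(rep(-57, 6), rep(-120, 4), rep(-57, 20), rep(-120, 4),
               rep(-57, 6))
  seg_psi <- function(d1, d2) c(rep(-47, 6), 130 + d1, rep(130, 3),
                                rep(-47, 20), 130 + d2, rep(130, 3),
                                rep(-47, 6))
  kind <- c(rep("helix", 6), rep("coil", 4), rep("helix", 20),
            rep("coil", 4), rep("helix", 6))
  sse <- confpath:::runs_to_ranges(kind)
  start <- make_chain(seg_phi, seg_psi(0, 0))
  goal <- make_chain(seg_phi, seg_psi(25, -35))
  topo <- build_topology(start, goal, sse = sse)
  list(topology = topo, start = start_conformation(topo),
       goal = goal_conformation(topo))
})

## A fake coarse structure with one residue per given CA position (N/C/O
## placed trivially nearby); geometry-only tests, not chemically sensible.
mk_point_structure <- function(ca_points) {
  coords <- lapply(seq_len(nrow(ca_points)), function(i) {
    ca <- ca_points[i, ]
    list(N = ca + c(-1.458, 0, 0), CA = ca,
         C = ca + c(0.5, 1.44, 0), O = ca + c(0.4, 2.0, 1.0),
         CB = ca + c(0.3, -1.2, 0.9))
  })
  confpath:::new_coarse_structure(rep("ALA", nrow(ca_points)), coords)
}

## Two copies of one helix as a two-element structure (chain break between
## them), the second transformed by R and t. Used for exact pair-geometry
## constructions.
two_helix_structure <- function(R = diag(3), t = c(10, 0, 0), n_res = 8L) {
  h <- make_helix(n_res)
  per_res <- function(s, i, xyz) {
    out <- list()
    for (nm in c("N", "CA", "C", "O", "CB")) {
      r <- s$idx[i, nm]
      if (!is.na(r)) out[[nm]] <- xyz[r, ]
    }
    out
  }
  xyz2 <- sweep(h$xyz %*% t(R), 2L, t, `+`)
  coords <- c(lapply(seq_len(n_res), function(i) per_res(h, i, h$xyz)),
              lapply(seq_len(n_res), function(i) per_res(h, i, xyz2)))
  s <- confpath:::new_coarse_structure(rep("ALA", 2L * n_res), coords)
  sse <- data.frame(kind = "helix", first = c(0L, n_res),
                    last = c(n_res - 1L, 2L * n_res - 1L))
  topo <- build_topology(s, s, sse = sse)
  start_conformation(topo)
}

## ---- independent oracles -------------------------------------------------

## Quaternion-eigenvalue least-RMSD (independent of the SVD route).
quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2L, colMeans(P))
  Q0 <- sweep(Q, 2L, colMeans(Q))
  M <- crossprod(P0, Q0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4L, 4L, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

## Quaternion-based point rotation (independent of the Rodrigues matrix).
quat_rotate <- function(xyz, point, axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  q <- c(cos(theta / 2), sin(theta / 2) * u)
  rot1 <- function(v) {
    w <- q[1]; qv <- q[2:4]
    v + 2 * w * pracma_cross(qv, v) +
      2 * pracma_cross(qv, pracma_cross(qv, v))
  }
  t(apply(xyz, 1L, function(p) rot1(p - point) + point))
}

## a stable vector perpendicular to ax
perp_vector <- function(ax) {
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  pracma_cross(ax, ref)
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

## Brute-force double-loop energy evaluation (no pair lists); mirrors the
## documented term definitions directly from the parameter object.
brute_force_energy <- function(conf, params) {
  s <- conf$topology$structure
  xyz <- conf$xyz
  M <- nrow(xyz)
  cls <- c(N = "N", CA = "CT", C = "C", O = "O", CB = "CT")[s$atom_name]
  soft_vdw <- 0
  for (i in 1:(M - 1)) for (j in (i + 1):M) {
    if (abs(s$atom_res[i] - s$atom_res[j]) < params$exclusion) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sig <- (params$lj_rmin_half[cls[i]] + params$lj_rmin_half[cls[j]]) /
           2^(1 / 6)
    eps <- sqrt(params$lj_eps[cls[i]] * params$lj_eps[cls[j]])
    x <- (sig / d)^6
    e <- 4 * eps * (x^2 - x)
    if (e > params$vdw_cap) e <- params$vdw_cap
    soft_vdw <- soft_vdw + e
  }
  sw <- function(d) {
    r <- params$hb_range; w <- params$hb_switch
    if (d >= r[1] && d <= r[2]) return(1)
    if (d < r[1] && d > r[1] - w)
      return(0.5 * (1 - cos(pi * (d - (r[1] - w)) / w)))
    if (d > r[2] && d < r[2] + w)
      return(0.5 * (1 + cos(pi * (d - r[2]) / w)))
    0
  }
  n <- length(s$aa)
  hbond <- 0
  for (i in 1:n) for (j in 1:n) {
    if (abs(i - j) < 3) next
    rn <- s$idx[i, "N"]; ro <- s$idx[j, "O"]
    if (is.na(rn) || is.na(ro)) next
    d <- sqrt(sum((xyz[rn, ] - xyz[ro, ])^2))
    hbond <- hbond - params$hb_epsilon * sw(d)
  }
  kd <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
          GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
          LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
          SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)
  cbr <- which(!is.na(s$idx[, "CB"]))
  burial <- 0; water <- 0
  if (length(cbr) >= 2) for (a in seq_along(cbr)) for (b in seq_along(cbr)) {
    if (a >= b) next
    i <- cbr[a]; j <- cbr[b]
    d <- sqrt(sum((xyz[s$idx[i, "CB"], ] - xyz[s$idx[j, "CB"], ])^2))
    if (d <= params$burial_radius) {
      burial <- burial - params$burial_weight * (kd[s$aa[i]] + kd[s$aa[j]])
    }
    if (d >= params$water_shell[1] && d <= params$water_shell[2])
      water <- water + params$water_eps * (kd[s$aa[i]] / 4.5) *
               (kd[s$aa[j]] / 4.5)
  }
  tb <- confpath:::energy_tables(conf$topology, params)
  bond <- 0
  if (!is.null(tb$bonds)) for (r in seq_len(nrow(tb$bonds))) {
    d <- sqrt(sum((xyz[tb$bonds[r, 1], ] - xyz[tb$bonds[r, 2], ])^2))
    bond <- bond + tb$bonds[r, 3] * (d - tb$bonds[r, 4])^2
  }
  angle <- 0
  if (!is.null(tb$angles)) for (r in seq_len(nrow(tb$angles))) {
    a <- xyz[tb$angles[r, 1], ]; b <- xyz[tb$angles[r, 2], ]
    cc <- xyz[tb$angles[r, 3], ]
    th <- acos(max(-1, min(1, sum((a - b) * (cc - b)) /
                   (sqrt(sum((a - b)^2)) * sqrt(sum((cc - b)^2))))))
    angle <- angle + tb$angles[r, 4] * (th - tb$angles[r, 5])^2
  }
  out <- list(soft_vdw = soft_vdw, hbond = hbond, burial = burial,
              water = water, bond = bond, angle = angle,
              total = soft_vdw + hbond + burial + water + bond + angle)
  lapply(out, unname)
}

## element residues that never deform: the element minus all junction-window
## (DOF) residues, whose backbone is flexible by design
element_core_rows <- function(topo) {
  win <- unique(vapply(topo$dofs, `[[`, 0L, "residue"))
  lapply(topo$elements, function(res)
    confpath:::residue_rows(topo$structure, setdiff(res, win)))
}

## Download a PDB entry from RCSB (used only by checks that reproduce
## values from deposited structures; they fail without network access).
fetch_pdb <- function(id) {
  memo(paste0("pdb_", id), {
    path <- tempfile(fileext = ".pdb")
    utils::download.file(sprintf("https://files.rcsb.org/download/%s.pdb",
                                 toupper(id)),
                         path, quiet = TRUE, mode = "wb")
    readLines(path)
  })
}

## Rebuild a coarse structure restricted to the given residue numbers.
subset_structure <- function(s, resnos) {
  keep <- which(s$resno %in% resnos)
  coords <- lapply(keep, function(i) {
    out <- list()
    for (nm in c("N", "CA", "C", "O", "CB")) {
      r <- s$idx[i, nm]
      if (!is.na(r)) out[[nm]] <- s$xyz[r, ]
    }
    out
  })
  confpath:::new_coarse_structure(s$aa[keep], coords, s$resno[keep],
                                  s$chain)
}

## CA matrices paired on common residue numbers of two chains.
paired_ca <- function(s1, s2) {
  common <- intersect(s1$resno, s2$resno)
  r1 <- match(common, s1$resno); r2 <- match(common, s2$resno)
  list(a = s1$xyz[s1$idx[r1, "CA"], , drop = FALSE],
       b = s2$xyz[s2$idx[r2, "CA"], , drop = FALSE])
}
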