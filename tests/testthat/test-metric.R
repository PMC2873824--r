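test_that("element axes recover degenerate and ideal geometries", {
  toy <- toy2()
  expect_error(element_axis(
    start_conformation(build_topology(make_helix(4), make_helix(4),
      sse = data.frame(kind = "helix", first = 0, last = 3))), 1),
    NA)
  # ideal helix: axis within 2 degrees of the rise direction measured over
  # full turns (analytic construction: one turn = 3.6 residues)
  h <- make_helix(19)   # 5 turns
  conf <- start_conformation(build_topology(h, h,
    sse = data.frame(kind = "helix", first = 0, last = 18)))
  ax <- element_axis(conf, 1)
  ca <- h$xyz[confpath:::atom_rows(h, "CA"), ]
  turn <- ca[19, ] - ca[1, ]          # 18 residues = 5 exact turns
  ang <- acos(abs(sum(ax * turn / sqrt(sum(turn^2))))) * 180 / pi
  expect_lt(ang, 2)
  # helix axes are oriented N- to C-terminal
  expect_gt(sum(ax * turn), 0)
})

test_that("plane normals are perpendicular to coplanar point sets", {
  # flatten a fake element onto a plane
  pts <- cbind(runif(8, 0, 10), runif(8, 0, 10), 0)
  s <- mk_point_structure(pts)
  sse <- data.frame(kind = "sheet", first = 0, last = 7)
  topo <- build_topology(s, s, sse = sse)
  # overwrite all atom coordinates to be exactly coplanar
  conf <- start_conformation(topo)
  conf$xyz[, 3] <- 0
  # give CA rows the in-plane positions
  ax <- element_axis(conf, 1)
  ca <- conf$xyz[confpath:::atom_rows(topo$structure, "CA"), ]
  diffs <- sweep(ca[-1, ], 2, ca[1, ])
  expect_lt(max(abs(diffs %*% ax)), 1e-10)
})

test_that("pair geometry matches exact constructions and is symmetric", {
  conf_par <- two_helix_structure(diag(3), c(10, 0, 0))
  pg <- pair_geometry(conf_par, 1, 2)
  expect_equal(pg$alpha, 0, tolerance = 1e-9)
  expect_equal(pg$dist, 10, tolerance = 1e-9)

  h <- make_helix(8)
  ax0 <- element_axis(start_conformation(build_topology(h, h,
    sse = data.frame(kind = "helix", first = 0, last = 7))), 1)
  # rotate the copy by 90 degrees about an axis perpendicular to its own
  perp <- confpath:::unit(perp_vector(ax0))
  R <- confpath:::rotation_matrix(perp, pi / 2)
  conf_perp <- two_helix_structure(R, c(20, 0, 5))
  pg2 <- pair_geometry(conf_perp, 1, 2)
  expect_equal(pg2$alpha, pi / 2, tolerance = 0.02)

  pg_ij <- pair_geometry(conf_perp, 1, 2)
  pg_ji <- pair_geometry(conf_perp, 2, 1)
  expect_equal(pg_ij$alpha, pg_ji$alpha)
  expect_equal(pg_ij$dist, pg_ji$dist)
})

test_that("element scores follow the stated weighted form", {
  toy <- toy2()
  conf <- apply_dihedral(toy$start, toy$hinge_dofs[1], 0.3)
  pc <- pair_geometry(conf, 1, 2)
  pg <- pair_geometry(toy$goal, 1, 2)
  expected <- 5 * abs(pc$alpha - pg$alpha) + 1 * abs(pc$dist - pg$dist)
  expect_equal(element_score(conf, 1, toy$goal), expected,
               tolerance = 1e-12)
  expect_equal(element_score(conf, 2, toy$goal), expected,
               tolerance = 1e-12)
  # doubling the distance weight with zero angle difference doubles s_i
  mp2 <- metric_params(w_angle = 0, w_dist = 2)
  mp1 <- metric_params(w_angle = 0, w_dist = 1)
  expect_equal(element_score(conf, 1, toy$goal, mp2),
               2 * element_score(conf, 1, toy$goal, mp1))
  # squared form
  mps <- metric_params(form = "squared")
  expect_equal(element_score(conf, 1, toy$goal, mps),
               5 * (pc$alpha - pg$alpha)^2 + (pc$dist - pg$dist)^2,
               tolerance = 1e-12)
})

test_that("feature vectors vanish exactly at the goal", {
  toy <- toy2()
  expect_equal(feature_vector(toy$goal, toy$goal), c(0, 0))
  fv <- feature_vector(toy$start, toy$goal)
  expect_length(fv, 2L)
  expect_true(all(fv >= 0))
  t3 <- toy3_mid()
  expect_length(feature_vector(t3$start, t3$goal), 3L)
  expect_equal(feature_vector(t3$goal, t3$goal), c(0, 0, 0))
})

test_that("the conformation distance is a pseudometric anchored at the
           goal", {
  toy <- toy2()
  s <- toy$start; g <- toy$goal
  expect_equal(conf_distance(s, s, g), 0)
  expect_equal(conf_distance(g, s, g),
               sqrt(sum(feature_vector(s, g)^2)))
  set.seed(21)
  confs <- lapply(1:12, function(k) {
    conf <- s
    for (nm in sample(names(toy$topology$dofs), 3))
      conf <- apply_dihedral(conf, nm, runif(1, -0.6, 0.6))
    conf
  })
  for (k in 1:60) {
    tri <- sample(12, 3)
    d_ab <- conf_distance(confs[[tri[1]]], confs[[tri[2]]], g)
    d_bc <- conf_distance(confs[[tri[2]]], confs[[tri[3]]], g)
    d_ac <- conf_distance(confs[[tri[1]]], confs[[tri[3]]], g)
    expect_gte(d_ab, 0)
    expect_equal(d_ab, conf_distance(confs[[tri[2]]], confs[[tri[1]]], g))
    expect_lte(d_ac, d_ab + d_bc + 1e-12)
  }
})

test_that("zero distance does not imply identical coordinates", {
  toy <- toy2()
  moved <- toy$start
  # a global rigid transform changes coordinates but no relative geometry
  R <- confpath:::rotation_matrix(c(0, 1, 1), 0.9)
  moved$xyz <- sweep(toy$start$xyz %*% t(R), 2, c(4, 4, 4), `+`)
  expect_gt(max(abs(moved$xyz - toy$start$xyz)), 1)
  expect_equal(conf_distance(moved, toy$start, toy$goal), 0,
               tolerance = 1e-9)
})

test_that("normalized distance traces the transition from 1 to 0", {
  toy <- toy2()
  expect_equal(normalized_distance(toy$start, toy$start, toy$goal), 1)
  expect_equal(normalized_distance(toy$goal, toy$start, toy$goal), 0)
  expect_error(normalized_distance(toy$start, toy$start, toy$start),
               "coincide")
  nd <- vapply(seq(0, 30, by = 1), function(d)
    normalized_distance(apply_dihedral(toy$start, toy$hinge_dofs[1],
                                       d * pi / 180),
                        toy$start, toy$goal), 0)
  mid <- nd[16]
  expect_gt(mid, 0); expect_lt(mid, 1)
  expect_gte(mean(diff(nd) < 0), 0.95)
})
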