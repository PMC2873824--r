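make_pdb_text <- function(rows) {
  vapply(seq_along(rows), function(k) {
    r <- rows[[k]]
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            k, sprintf(" %-3s", r$name), r$res, r$chain %||% "A", r$resno,
            r$x, r$y, r$z, r$occ %||% 1, 0,
            substr(r$name, 1L, 1L))
  }, "")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## ideal residue backbone positions reused across parsing fixtures
res_atoms <- function(resno, shift, res = "ALA", chain = "A", occ = 1,
                      with_cb = TRUE) {
  base <- list(
    list(name = "N", x = 0.000, y = 0, z = 0),
    list(name = "CA", x = 1.458, y = 0, z = 0),
    list(name = "C", x = 2.009, y = 1.420, z = 0),
    list(name = "O", x = 1.251, y = 2.390, z = 0))
  if (with_cb) base <- c(base, list(list(name = "CB", x = 1.988, y = -0.773,
                                         z = -1.199)))
  lapply(base, function(a) {
    a$res <- res; a$chain <- chain; a$resno <- resno
    a$x <- a$x + shift; a$occ <- occ
    a
  })
}

test_that("a toy PDB parses into ordered coarse residues", {
  rows <- c(res_atoms(1, 0), res_atoms(2, 10), res_atoms(3, 20))
  s <- load_structure(make_pdb_text(rows))
  expect_s3_class(s, "coarse_structure")
  expect_equal(length(s$aa), 3L)
  expect_equal(s$resno, 1:3)
  expect_equal(s$atom_res[1], 0L)
  # far-apart residues are recorded as chain breaks
  expect_equal(s$breaks, c(0L, 1L))
})

test_that("glycine has no CB and a missing non-glycine CB is rebuilt", {
  rows <- c(res_atoms(1, 0, res = "GLY", with_cb = FALSE),
            res_atoms(2, 10, res = "ALA", with_cb = FALSE))
  s <- load_structure(make_pdb_text(rows))
  expect_true(is.na(s$idx[1, "CB"]))
  expect_false(is.na(s$idx[2, "CB"]))
  ca <- s$xyz[s$idx[2, "CA"], ]
  cb <- s$xyz[s$idx[2, "CB"], ]
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 0.011)

  # independent rotation-construction oracle for the ideal CB position:
  # angle N-CA-CB = 110.5 deg, dihedral C-N-CA-CB = +122.55 deg, 1.53 A
  n <- s$xyz[s$idx[2, "N"], ]; c3 <- s$xyz[s$idx[2, "C"], ]
  e1 <- (n - ca) / sqrt(sum((n - ca)^2))
  pc <- (c3 - ca) - sum((c3 - ca) * e1) * e1
  pc <- pc / sqrt(sum(pc^2))
  q <- pracma_cross(pc, -e1)   # completes the frame about the N-CA axis
  th <- 110.5 * pi / 180; chi <- 122.55 * pi / 180
  cb_oracle <- ca + 1.53 * (cos(th) * e1 +
                            sin(th) * (cos(chi) * pc + sin(chi) * q))
  # the oracle must itself satisfy the defining internal coordinates
  expect_equal(confpath:::dihedral(c3, n, ca, cb_oracle) * 180 / pi,
               122.55, tolerance = 1e-6)
  expect_equal(max(abs(cb_oracle - cb)), 0, tolerance = 1e-6)
  # L-chirality: positive signed volume of the (N, C, CB) frame at CA
  expect_gt(det(cbind(n - ca, c3 - ca, cb - ca)), 0)
})

test_that("alternate locations resolve to the highest occupancy", {
  rows <- c(res_atoms(1, 0, occ = 0.4), res_atoms(1, 100, occ = 0.6))
  s <- suppressWarnings(load_structure(make_pdb_text(rows)))
  expect_equal(length(s$aa), 1L)
  expect_equal(s$xyz[s$idx[1, "N"], 1], 100)
})

test_that("unparseable input is a fatal error", {
  expect_error(load_structure("REMARK nothing here"), "parse|ATOM")
  rows <- res_atoms(1, 0)
  expect_error(load_structure(make_pdb_text(rows), chain = "Z"), "chain")
})

test_that("header HELIX/SHEET records convert verbatim and clip", {
  h <- make_helix(30)
  hdr <- sprintf("HELIX    1   1 ALA A    6  ALA A   21  1          16")
  sse <- assign_sse(h, header_records = hdr)
  hel <- sse[sse$kind == "helix", ]
  expect_equal(nrow(hel), 1L)
  expect_equal(c(hel$first, hel$last), c(5L, 20L))   # resno 6..21, 0-based
  # range beyond the chain is clipped with a warning
  hdr2 <- sprintf("HELIX    1   1 ALA A   25  ALA A   99  1          16")
  expect_warning(sse2 <- assign_sse(h, header_records = hdr2), "clip")
  expect_equal(max(sse2$last), 29L)
})

test_that("the dihedral heuristic labels ideal helix and extended chains", {
  h <- make_helix(12)
  sse <- assign_sse(h)
  hel <- sse[sse$kind == "helix", ]
  expect_equal(nrow(hel), 1L)
  expect_equal(c(hel$first, hel$last), c(1L, 10L))   # interior residues
  ext <- make_chain(rep(-120, 8), rep(130, 8))
  sse2 <- assign_sse(ext)
  expect_equal(sum(sse2$kind == "sheet"), 1L)
  expect_equal(sum(sse2$kind == "helix"), 0L)
})

test_that("rigid-element assignment splits loops by proximity with a
           deterministic tie-break", {
  kind <- c(rep("helix", 10), rep("coil", 4), rep("helix", 10))
  sse <- confpath:::runs_to_ranges(kind)
  s <- make_helix(24)   # geometry irrelevant to the partition logic
  el <- assign_rigid_elements(sse, s)
  expect_equal(el[[1]], 0:11)          # 2 loop residues left
  expect_equal(el[[2]], 12:23)         # 2 loop residues right
  # odd loop: middle residue goes to the preceding element
  kind3 <- c(rep("helix", 10), rep("coil", 3), rep("helix", 10))
  el3 <- assign_rigid_elements(confpath:::runs_to_ranges(kind3),
                               make_helix(23))
  expect_equal(el3[[1]], 0:11)
  expect_equal(el3[[2]], 12:22)
  # merging all elements gives the whole chain
  elm <- assign_rigid_elements(sse, s, merge_groups = list(c(1, 2)))
  expect_equal(length(elm), 1L)
  expect_equal(elm[[1]], 0:23)
  # no SSEs at all: whole chain with a warning
  coil <- confpath:::runs_to_ranges(rep("coil", 24))
  expect_warning(el0 <- assign_rigid_elements(coil, s), "one rigid element")
  expect_equal(el0[[1]], 0:23)
})

test_that("rigid elements always partition the chain", {
  set.seed(7)
  for (rep in 1:20) {
    n_sse <- sample(1:4, 1)
    kind <- unlist(lapply(seq_len(n_sse), function(k)
      c(rep(sample(c("helix", "sheet"), 1), sample(3:8, 1)),
        rep("coil", sample(0:5, 1)))))
    kind <- c(rep("coil", sample(0:3, 1)), kind)
    n <- length(kind)
    el <- suppressWarnings(
      assign_rigid_elements(confpath:::runs_to_ranges(kind), make_helix(n)))
    expect_equal(sort(unlist(el)), 0:(n - 1))
  }
})

test_that("pathway output roundtrips through PDB text", {
  toy <- toy2()
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_pathway(list(), f), "empty")
  write_pathway(list(toy$start), f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 1L)
  path <- list(toy$start, toy$goal, toy$start, toy$goal, toy$start)
  write_pathway(path, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 5L)
  ms <- load_pathway(f)
  expect_equal(length(ms), 5L)
  s0 <- toy$topology$structure
  expect_equal(ms[[1]]$aa, s0$aa)
  expect_equal(length(ms[[1]]$aa), length(s0$aa))
  expect_lt(max(abs(ms[[2]]$xyz - toy$goal$xyz)), 1e-3 + 1e-9)
})
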