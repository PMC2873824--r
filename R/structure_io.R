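## Coarse backbone + C-beta structures: parsing from PDB, secondary-structure
## assignment, grouping into rigid elements, and multi-model pathway output.

## Ideal backbone geometry used for fixture construction and CB rebuilding.
## Lengths in Angstrom, angles in degrees.
.ideal <- list(
  b_n_ca = 1.458, b_ca_c = 1.523, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.53,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.6,
  ang_ca_c_o = 120.4, ang_n_ca_cb = 110.5,
  improper_cb = 122.55,   # dihedral C-N-CA-CB giving the L configuration
  omega = 180
)

.atom_names <- c("N", "CA", "C", "O", "CB")

## Ideal tetrahedral CB position from the backbone N, CA, C of one residue.
ideal_cb <- function(n, ca, c) {
  place_atom(c, n, ca, .ideal$b_ca_cb,
             deg2rad(.ideal$ang_n_ca_cb), deg2rad(.ideal$improper_cb))
}

#' Construct a coarse structure from per-residue atom coordinates
#'
#' Internal constructor shared by the PDB reader and the synthetic-structure
#' generators. Residues are held in chain order with 0-based `seq_index`;
#' atoms are stacked into a single coordinate matrix with an index table
#' mapping (residue, atom name) to rows.
#'
#' @param aa character vector of three-letter residue codes.
#' @param coords list, one entry per residue, each a named list with `N`,
#'   `CA`, `C`, `O` and optionally `CB` coordinate vectors.
#' @param resno original PDB residue numbers (kept for output only).
#' @param chain one-character chain identifier.
#' @return An object of class `coarse_structure`.
#' @keywords internal
new_coarse_structure <- function(aa, coords, resno = seq_along(aa),
                                 chain = "A") {
  n <- length(aa)
  stopifnot(length(coords) == n)
  idx <- matrix(NA_integer_, n, 5L, dimnames = list(NULL, .atom_names))
  rows <- vector("list", n)
  k <- 0L
  for (i in seq_len(n)) {
    at <- coords[[i]]
    res_rows <- NULL
    for (nm in .atom_names) {
      if (!is.null(at[[nm]])) {
        k <- k + 1L
        idx[i, nm] <- k
        res_rows <- rbind(res_rows, at[[nm]])
      }
    }
    rows[[i]] <- res_rows
  }
  xyz <- do.call(rbind, rows)
  dimnames(xyz) <- NULL
  atom_res <- rep.int(seq_len(n) - 1L, vapply(rows, nrow, 0L))
  atom_name <- unlist(lapply(seq_len(n), function(i)
    .atom_names[!is.na(idx[i, ])]), use.names = FALSE)
  s <- list(aa = toupper(aa), resno = as.integer(resno), chain = chain,
            xyz = xyz, idx = idx, atom_res = atom_res, atom_name = atom_name,
            breaks = integer(0))
  class(s) <- "coarse_structure"
  s$breaks <- find_breaks(s)
  s
}

## 0-based indices i such that the chain is discontinuous between residues
## i and i+1 (peptide C(i)-N(i+1) longer than 2 Angstrom).
find_breaks <- function(s) {
  n <- length(s$aa)
  if (n < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(n - 1L)) {
    ci <- s$idx[i, "C"]; ni <- s$idx[i + 1L, "N"]
    if (is.na(ci) || is.na(ni) ||
        vnorm(s$xyz[ci, ] - s$xyz[ni, ]) > 2.0)
      out <- c(out, i - 1L)
  }
  out
}

n_residues <- function(s) length(s$aa)

## Coordinate of one named atom of residue i (0-based); NULL if absent.
atom_xyz <- function(s, i, name, xyz = s$xyz) {
  r <- s$idx[i + 1L, name]
  if (is.na(r)) return(NULL)
  xyz[r, ]
}

## All atom rows belonging to the given 0-based residue indices.
residue_rows <- function(s, res) which(s$atom_res %in% res)

## Rows of one atom type across the chain (e.g. all CA).
atom_rows <- function(s, name) {
  r <- s$idx[, name]
  r[!is.na(r)]
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat(sprintf("coarse_structure: %d residues, chain %s, %d atoms, %d break(s)\n",
              n_residues(x), x$chain, nrow(x$xyz), length(x$breaks)))
  invisible(x)
}

#' Load a PDB chain as a coarse backbone + C-beta structure
#'
#' Parses ATOM records (via bio3d), keeping only the N, CA, C, O and CB
#' atoms. Residues missing any of N/CA/C are dropped with a warning; a
#' missing CB on a non-glycine residue is rebuilt at the ideal tetrahedral
#' position from N/CA/C. Alternate locations are resolved by highest
#' occupancy (ties: first encountered). Chain breaks are recorded wherever
#' the peptide C(i)-N(i+1) distance exceeds 2 Angstrom.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param chain chain identifier; defaults to the first chain present.
#' @return A `coarse_structure`.
#' @export
load_structure <- function(pdb, chain = NULL) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1L], fixed = TRUE) ||
      !file.exists(pdb[1L])) {
    lines <- if (length(pdb) == 1L) strsplit(pdb, "\n", fixed = TRUE)[[1L]]
             else pdb
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
  }
  p <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE,
                                rm.alt = FALSE),
                error = function(e) stop("cannot parse PDB input: ",
                                         conditionMessage(e)))
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in PDB input")
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain)
  at <- at[at$elety %in% .atom_names, , drop = FALSE]
  if (nrow(at) == 0L) stop("no parseable backbone atoms for chain ", chain)

  ins <- at$insert
  ins[is.na(ins)] <- ""
  rid <- paste0(at$resno, "_", ins)
  occ <- at$o
  occ[is.na(occ)] <- 1

  ures <- unique(rid)                      # order of appearance
  coords <- list(); aa <- character(0); resno <- integer(0)
  dropped <- 0L
  for (u in ures) {
    sel <- which(rid == u)
    atoms <- list()
    for (nm in .atom_names) {
      s2 <- sel[at$elety[sel] == nm]
      if (length(s2) == 0L) next
      s2 <- s2[order(-occ[s2])][1L]        # highest occupancy, ties first
      atoms[[nm]] <- c(at$x[s2], at$y[s2], at$z[s2])
    }
    res_aa <- toupper(at$resid[sel[1L]])
    if (is.null(atoms$N) || is.null(atoms$CA) || is.null(atoms$C)) {
      dropped <- dropped + 1L
      next
    }
    # internal geometry sanity for accepted residues
    if (vnorm(atoms$CA - atoms$N) < 1.2 || vnorm(atoms$CA - atoms$N) > 1.7 ||
        vnorm(atoms$C - atoms$CA) < 1.3 || vnorm(atoms$C - atoms$CA) > 1.8) {
      dropped <- dropped + 1L
      next
    }
    if (res_aa == "GLY") {
      atoms$CB <- NULL
    } else if (is.null(atoms$CB)) {
      atoms$CB <- ideal_cb(atoms$N, atoms$CA, atoms$C)
    }
    aa <- c(aa, res_aa)
    resno <- c(resno, at$resno[sel[1L]])
    coords[[length(coords) + 1L]] <- atoms
  }
  if (dropped > 0L)
    warning(dropped, " residue(s) dropped (incomplete or distorted backbone)")
  if (length(aa) == 0L) stop("no complete residues parsed")
  new_coarse_structure(aa, coords, resno, chain)
}

## phi/psi per residue (radians); NA where undefined (termini, breaks).
backbone_dihedrals <- function(s, xyz = s$xyz) {
  n <- n_residues(s)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  brk <- s$breaks
  for (i in seq_len(n)) {
    i0 <- i - 1L
    if (i > 1L && !((i0 - 1L) %in% brk)) {
      p <- list(atom_xyz(s, i0 - 1L, "C", xyz), atom_xyz(s, i0, "N", xyz),
                atom_xyz(s, i0, "CA", xyz), atom_xyz(s, i0, "C", xyz))
      if (!any(vapply(p, is.null, TRUE)))
        phi[i] <- dihedral(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
    }
    if (i < n && !(i0 %in% brk)) {
      p <- list(atom_xyz(s, i0, "N", xyz), atom_xyz(s, i0, "CA", xyz),
                atom_xyz(s, i0, "C", xyz), atom_xyz(s, i0 + 1L, "N", xyz))
      if (!any(vapply(p, is.null, TRUE)))
        psi[i] <- dihedral(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
    }
  }
  cbind(phi = phi, psi = psi)
}

#' Assign secondary-structure elements
#'
#' If PDB HELIX/SHEET header records are supplied they are converted
#' verbatim (ranges outside the chain are clipped with a warning).
#' Otherwise a backbone-dihedral heuristic is used: at least `min_helix`
#' consecutive residues with phi in `helix_phi` and psi in `helix_psi`
#' become a helix; at least `min_sheet` consecutive residues in the extended
#' ranges become a sheet. Unassigned runs are labelled coil.
#'
#' @param structure a `coarse_structure`.
#' @param header_records optional character vector (or single string) of PDB
#'   lines containing HELIX/SHEET records.
#' @param helix_phi,helix_psi,sheet_phi,sheet_psi inclusive degree ranges for
#'   the heuristic.
#' @param min_helix,min_sheet minimum run lengths.
#' @return data.frame with columns `kind` ("helix"/"sheet"/"coil") and
#'   0-based inclusive `first`, `last`; rows sorted and non-overlapping,
#'   covering the whole chain.
#' @export
assign_sse <- function(structure, header_records = NULL,
                       helix_phi = c(-100, -30), helix_psi = c(-80, -5),
                       sheet_phi = c(-180, -90), sheet_psi = c(90, 180),
                       min_helix = 4L, min_sheet = 3L) {
  n <- n_residues(structure)
  stopifnot(n > 0L)
  kind <- rep("coil", n)

  from_header <- FALSE
  if (!is.null(header_records)) {
    lines <- if (length(header_records) == 1L)
      strsplit(header_records, "\n", fixed = TRUE)[[1L]] else header_records
    recs <- parse_sse_header(lines, structure$chain)
    if (nrow(recs) > 0L) {
      from_header <- TRUE
      for (r in seq_len(nrow(recs))) {
        first <- match(recs$start[r], structure$resno) - 1L
        last <- match(recs$end[r], structure$resno) - 1L
        if (is.na(first) || is.na(last)) {
          # clip to chain
          keep <- which(structure$resno >= recs$start[r] &
                        structure$resno <= recs$end[r])
          if (length(keep) == 0L) {
            warning("header SSE record outside chain ignored")
            next
          }
          warning("header SSE range clipped to chain")
          first <- min(keep) - 1L; last <- max(keep) - 1L
        }
        kind[(first:last) + 1L] <- recs$kind[r]
      }
    }
  }

  if (!from_header) {
    pp <- rad2deg(backbone_dihedrals(structure))
    in_rng <- function(x, r) !is.na(x) & x >= r[1L] & x <= r[2L]
    hel <- in_rng(pp[, 1L], helix_phi) & in_rng(pp[, 2L], helix_psi)
    sht <- in_rng(pp[, 1L], sheet_phi) & in_rng(pp[, 2L], sheet_psi)
    kind[mark_runs(hel, min_helix)] <- "helix"
    kind[mark_runs(sht, min_sheet) & kind == "coil"] <- "sheet"
  }

  runs_to_ranges(kind)
}

## logical vector -> logical marking positions inside runs of length >= m
mark_runs <- function(flag, m) {
  r <- rle(flag)
  keep <- r$values & r$lengths >= m
  rep.int(keep, r$lengths)
}

runs_to_ranges <- function(kind) {
  r <- rle(kind)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.frame(kind = r$values, first = first - 1L, last = last - 1L,
             stringsAsFactors = FALSE)
}

parse_sse_header <- function(lines, chain) {
  out <- data.frame(kind = character(0), start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  for (ln in lines) {
    rec <- substr(ln, 1L, 6L)
    if (rec == "HELIX ") {
      ch <- substr(ln, 20L, 20L)
      if (ch != chain) next
      out <- rbind(out, data.frame(
        kind = "helix",
        start = as.integer(substr(ln, 22L, 25L)),
        end = as.integer(substr(ln, 34L, 37L)), stringsAsFactors = FALSE))
    } else if (rec == "SHEET ") {
      ch <- substr(ln, 22L, 22L)
      if (ch != chain) next
      out <- rbind(out, data.frame(
        kind = "sheet",
        start = as.integer(substr(ln, 23L, 26L)),
        end = as.integer(substr(ln, 34L, 37L)), stringsAsFactors = FALSE))
    }
  }
  out
}

#' Group residues into rigid elements
#'
#' Each helix/sheet annotation seeds one rigid element; every coil residue is
#' appended to the element whose nearest end is fewest residues away in
#' sequence (ties go to the preceding, N-terminal element). Terminal coils
#' attach to the adjacent element. `merge_groups` unions the listed elements
#' (1-based ids in annotation order) into single rigid elements, e.g. when
#' several elements are known not to move relative to each other.
#'
#' @param sses data.frame as returned by [assign_sse()].
#' @param structure the `coarse_structure` the annotations refer to.
#' @param merge_groups optional list of integer vectors of element ids.
#' @return list of 0-based residue-index vectors, one per rigid element,
#'   partitioning the chain; attribute `kind` holds "helix" or "plane" per
#'   element (plane = sheet, merged or mixed content, measured by a
#'   least-squares plane in the metric).
#' @export
assign_rigid_elements <- function(sses, structure, merge_groups = NULL) {
  n <- n_residues(structure)
  core <- sses[sses$kind != "coil", , drop = FALSE]
  if (nrow(core) == 0L) {
    warning("no secondary structure elements; whole chain as one rigid element")
    out <- list(0:(n - 1L))
    attr(out, "kind") <- "plane"
    return(out)
  }
  ne <- nrow(core)
  member <- rep(NA_integer_, n)
  for (e in seq_len(ne)) member[(core$first[e]:core$last[e]) + 1L] <- e

  for (i in which(is.na(member))) {
    i0 <- i - 1L
    prev_e <- if (any(core$last < i0)) max(which(core$last < i0)) else NA
    next_e <- if (any(core$first > i0)) min(which(core$first > i0)) else NA
    if (is.na(prev_e)) { member[i] <- next_e; next }
    if (is.na(next_e)) { member[i] <- prev_e; next }
    dl <- i0 - core$last[prev_e]
    dr <- core$first[next_e] - i0
    member[i] <- if (dl <= dr) prev_e else next_e   # tie -> preceding
  }

  group_of <- seq_len(ne)
  if (!is.null(merge_groups)) {
    for (g in merge_groups) {
      g <- sort(unique(as.integer(g)))
      stopifnot(all(g >= 1L & g <= ne))
      group_of[group_of %in% group_of[g]] <- min(group_of[g])
    }
  }
  ugr <- sort(unique(group_of))
  out <- vector("list", length(ugr))
  kinds <- character(length(ugr))
  for (k in seq_along(ugr)) {
    els <- which(group_of == ugr[k])
    out[[k]] <- sort(which(member %in% els)) - 1L
    kk <- core$kind[els]
    kinds[k] <- if (length(kk) == 1L && kk == "helix") "helix" else "plane"
  }
  attr(out, "kind") <- kinds
  out
}

#' Write a conformational pathway as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per conformation, coordinates to three decimals.
#' The output is readable back with [load_structure()] (first model) or
#' [load_pathway()] (all models).
#'
#' @param path list of `conformation` objects (or coordinate matrices paired
#'   with `structure`) sharing one topology.
#' @param file output path.
#' @param structure the `coarse_structure` giving residue/atom naming; taken
#'   from the first conformation's topology when omitted.
#' @return `file`, invisibly.
#' @export
write_pathway <- function(path, file, structure = NULL) {
  if (length(path) == 0L) stop("empty pathway")
  if (is.null(structure)) {
    if (!inherits(path[[1L]], "conformation"))
      stop("structure must be supplied for raw coordinate input")
    structure <- path[[1L]]$topology$structure
  }
  con <- base::file(file, "w")
  on.exit(close(con))
  elem <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  for (m in seq_along(path)) {
    xyz <- if (inherits(path[[m]], "conformation")) path[[m]]$xyz
           else path[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- character(nrow(xyz))
    for (a in seq_len(nrow(xyz))) {
      i <- structure$atom_res[a] + 1L
      nm <- structure$atom_name[a]
      lines[a] <- sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a, sprintf(" %-3s", nm), structure$aa[i], structure$chain,
        structure$resno[i], xyz[a, 1L], xyz[a, 2L], xyz[a, 3L], 1, 0,
        elem[[nm]])
    }
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read all models of a multi-model PDB file
#'
#' @param pdb path or character vector of PDB lines.
#' @param chain chain identifier (default: first chain).
#' @return list of `coarse_structure`, one per MODEL (a single list element
#'   for single-model files).
#' @export
load_pathway <- function(pdb, chain = NULL) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb[1L], fixed = TRUE) &&
               file.exists(pdb[1L])) readLines(pdb)
           else if (length(pdb) == 1L) strsplit(pdb, "\n", fixed = TRUE)[[1L]]
           else pdb
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(load_structure(lines, chain)))
  ends <- grep("^ENDMDL", lines)
  stopifnot(length(starts) == length(ends))
  lapply(seq_along(starts), function(k)
    load_structure(lines[(starts[k] + 1L):(ends[k] - 1L)], chain))
}
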