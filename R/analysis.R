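## Pathway post-processing: CA least RMSD, the delta-D-RMSD and hinge-angle
## reaction coordinates, binned pseudo-free-energy profiles, and
## path-against-reference comparison.

## CA coordinate matrix from a conformation, coarse structure or matrix.
ca_coords <- function(x) {
  if (inherits(x, "conformation"))
    return(x$xyz[atom_rows(x$topology$structure, "CA"), , drop = FALSE])
  if (inherits(x, "coarse_structure"))
    return(x$xyz[atom_rows(x, "CA"), , drop = FALSE])
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop("cannot extract CA coordinates from this object")
}

#' Least RMSD between two conformations
#'
#' Root-mean-square deviation over CA atoms (paired by residue index) after
#' optimal rigid superposition (Kabsch; proper rotations only, reflections
#' excluded).
#'
#' @param a,b conformations, coarse structures, or CA coordinate matrices
#'   with equal row counts.
#' @return RMSD in Angstrom.
#' @export
lrmsd <- function(a, b) {
  P <- ca_coords(a); Q <- ca_coords(b)
  if (nrow(P) != nrow(Q)) stop("CA counts differ; cannot pair residues")
  kabsch(P, Q)$rmsd
}

#' Delta-D-RMSD reaction coordinate
#'
#' `lrmsd(c, open) - lrmsd(c, closed)`: negative near the open state,
#' positive near the closed state.
#'
#' @param c,open,closed conformations (or CA matrices) with a shared
#'   residue pairing.
#' @return Angstrom.
#' @export
delta_d_rmsd <- function(c, open, closed) lrmsd(c, open) - lrmsd(c, closed)

#' Inter-domain hinge angle
#'
#' The angle at the hinge center of mass between the vectors to the
#' N-terminal and C-terminal domain centers of mass.
#'
#' @param conf a `conformation` or `coarse_structure`.
#' @param domains list with 0-based residue index vectors `n_domain`,
#'   `c_domain`, `hinge` (disjoint).
#' @param atoms "all" (all retained atoms) or "ca".
#' @return angle in degrees, in [0, 180].
#' @export
theta_angle <- function(conf, domains, atoms = c("all", "ca")) {
  atoms <- match.arg(atoms)
  s <- if (inherits(conf, "conformation")) conf$topology$structure else conf
  xyz <- if (inherits(conf, "conformation")) conf$xyz else conf$xyz
  stopifnot(length(domains$n_domain) > 0L, length(domains$c_domain) > 0L,
            length(domains$hinge) > 0L)
  if (length(intersect(domains$n_domain, domains$c_domain)) ||
      length(intersect(domains$n_domain, domains$hinge)) ||
      length(intersect(domains$c_domain, domains$hinge)))
    stop("domain residue sets must be disjoint")
  com_of <- function(res) {
    rows <- if (atoms == "all") residue_rows(s, res)
            else { r <- s$idx[res + 1L, "CA"]; r[!is.na(r)] }
    colMeans(xyz[rows, , drop = FALSE])
  }
  cm_n <- com_of(domains$n_domain)
  cm_c <- com_of(domains$c_domain)
  cm_h <- com_of(domains$hinge)
  if (vnorm(cm_n - cm_h) < 1e-9 || vnorm(cm_c - cm_h) < 1e-9)
    stop("degenerate domain geometry (coincident centers of mass)")
  rad2deg(bond_angle(cm_n, cm_h, cm_c))
}

#' Binned pseudo-free-energy profile along a reaction coordinate
#'
#' Pathway samples are first decimated so that consecutive retained samples
#' of the same pathway are at least `spacing` apart in the metric
#' coordinate (decorrelation), then binned; each non-empty bin gets
#' `-ln(count / total)`. Empty bins are masked as `NA` rather than
#' infinite. The profile depends on sample density only, so duplicating
#' the whole sample set leaves it unchanged.
#'
#' @param samples numeric vector of reaction-coordinate values, or a
#'   data.frame with columns `value`, and optionally `path` (pathway id)
#'   and `pos` (metric position along the pathway) enabling the
#'   decorrelating subsampling.
#' @param bins number of bins (over the sample range).
#' @param spacing minimum metric spacing between retained samples of one
#'   pathway (default 1 distance unit).
#' @return data.frame with bin `mid`, `count` and pseudo-free-energy
#'   `value` (units of kT).
#' @export
pmf_profile <- function(samples, bins = 20L, spacing = 1) {
  if (is.numeric(samples)) samples <- data.frame(value = samples)
  stopifnot(is.data.frame(samples), "value" %in% names(samples))
  vals <- samples$value
  if (!is.null(samples$path) && !is.null(samples$pos)) {
    keep <- logical(nrow(samples))
    for (p in unique(samples$path)) {
      rows <- which(samples$path == p)
      rows <- rows[order(samples$pos[rows])]
      last <- -Inf
      for (r in rows) {
        if (samples$pos[r] >= last + spacing) { keep[r] <- TRUE
                                                last <- samples$pos[r] }
      }
    }
    vals <- samples$value[keep]
  }
  stopifnot(all(is.finite(vals)))
  rng <- range(vals)
  if (diff(rng) <= 0) stop("all samples fall in one bin; no profile")
  edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  cnt <- as.vector(table(cut(vals, edges, include.lowest = TRUE)))
  if (sum(cnt > 0) < 2L) stop("all samples fall in one bin; no profile")
  value <- ifelse(cnt > 0, -log(cnt / length(vals)), NA_real_)
  data.frame(mid = (edges[-1L] + edges[-(bins + 1L)]) / 2,
             count = cnt, value = value)
}

#' Compare a pathway against a reference pathway
#'
#' For each conformation of `p`, the least RMSD to its nearest neighbour
#' along `q`, with summary statistics (paths tend to agree near their
#' endpoints and deviate most in the middle).
#'
#' @param p,q lists of conformations (or CA matrices) with a shared
#'   topology.
#' @return list with `per_conf` (numeric vector along `p`), `max`, `mean`
#'   and `endpoint` (value at the last conformation of `p`).
#' @export
compare_paths <- function(p, q) {
  if (length(p) == 0L || length(q) == 0L) stop("empty pathway")
  qca <- lapply(q, ca_coords)
  per <- vapply(p, function(ci) {
    pca <- ca_coords(ci)
    min(vapply(qca, function(cj) kabsch(pca, cj)$rmsd, 0))
  }, 0)
  list(per_conf = per, max = max(per), mean = mean(per),
       endpoint = per[length(per)])
}
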