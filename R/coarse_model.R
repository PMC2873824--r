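## SSE-level articulation model: the element graph G = (V, E), the spanning
## tree rooted at the least-moving element, the mobile set K, and the loop
## dihedral degrees of freedom.

#' Build the rigid-element adjacency graph
#'
#' Two rigid elements are connected iff some pair of sequentially adjacent
#' residues falls one in each element and not across a chain break. Multiple
#' adjacent pairs between the same two elements collapse to a single edge
#' (first junction kept; all junction residues recorded).
#'
#' @param elements rigid-element residue ranges from [assign_rigid_elements()].
#' @param structure the `coarse_structure`.
#' @return list with `n_nodes`, `edges` (data.frame `a`, `b`, `r1`, `r2`;
#'   `a < b`, junction residues 0-based) and `junctions` (list of matrices of
#'   all adjacent pairs per edge).
#' @export
build_graph <- function(elements, structure) {
  n <- n_residues(structure)
  ne <- length(elements)
  member <- element_membership(elements, n)
  edges <- data.frame(a = integer(0), b = integer(0),
                      r1 = integer(0), r2 = integer(0))
  junctions <- list()
  if (n >= 2L) for (i in 0:(n - 2L)) {
    if (i %in% structure$breaks) next
    e1 <- member[i + 1L]; e2 <- member[i + 2L]
    if (e1 == e2) next
    a <- min(e1, e2); b <- max(e1, e2)
    hit <- which(edges$a == a & edges$b == b)
    if (length(hit) == 0L) {
      edges <- rbind(edges, data.frame(a = a, b = b, r1 = i, r2 = i + 1L))
      junctions[[length(junctions) + 1L]] <- cbind(i, i + 1L)
    } else {
      junctions[[hit]] <- rbind(junctions[[hit]], c(i, i + 1L))
    }
  }
  list(n_nodes = ne, edges = edges, junctions = junctions)
}

element_membership <- function(elements, n) {
  member <- rep(NA_integer_, n)
  for (e in seq_along(elements)) member[elements[[e]] + 1L] <- e
  stopifnot(!anyNA(member))
  member
}

#' Build the spanning tree of the element graph
#'
#' The root is the rigid element expected to move least: after a whole-chain
#' Kabsch alignment of start onto goal, the element with the smallest
#' per-element CA RMSD (ties: lowest element id). The tree is grown greedily
#' breadth-first from the root, visiting neighbours in increasing element-id
#' order. A disconnected graph yields one tree per component with roots
#' chosen independently.
#'
#' @param graph from [build_graph()].
#' @param start,goal the two `coarse_structure` end states (same topology).
#' @param elements the rigid-element ranges.
#' @return list with `roots` (element ids), `parent` (integer vector, NA at
#'   roots), `junction` (n_elements x 2 matrix of the junction residue pair
#'   on the edge to the parent) and `order` (BFS visit order).
#' @export
build_spanning_tree <- function(graph, start, goal, elements) {
  ne <- graph$n_nodes
  # rounded so that exact ties (identical elements) resolve by element id
  per_rmsd <- round(element_displacement(start, goal, elements), 6L)

  adj <- vector("list", ne)
  for (k in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[k]; b <- graph$edges$b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- rep(NA_integer_, ne)
  cid <- 0L
  for (v in seq_len(ne)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, adj[[u]])
    }
  }

  parent <- rep(NA_integer_, ne)
  junction <- matrix(NA_integer_, ne, 2L)
  roots <- integer(0)
  visited <- rep(FALSE, ne)
  for (cc in seq_len(cid)) {
    members <- which(comp == cc)
    root <- members[order(per_rmsd[members], members)][1L]
    roots <- c(roots, root)
    queue <- root
    visited[root] <- TRUE
    order_in <- root
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in sort(adj[[u]])) {
        if (visited[v]) next
        visited[v] <- TRUE
        parent[v] <- u
        k <- which((graph$edges$a == min(u, v)) & (graph$edges$b == max(u, v)))
        junction[v, ] <- c(graph$edges$r1[k], graph$edges$r2[k])
        queue <- c(queue, v)
        order_in <- c(order_in, v)
      }
    }
  }
  list(roots = roots, parent = parent, junction = junction,
       order = which(visited))
}

## Per-element CA RMSD between start and goal after whole-structure alignment.
element_displacement <- function(start, goal, elements) {
  ca_s <- start$xyz[atom_rows(start, "CA"), , drop = FALSE]
  ca_g <- goal$xyz[atom_rows(goal, "CA"), , drop = FALSE]
  stopifnot(nrow(ca_s) == nrow(ca_g))
  fit <- kabsch(ca_s, ca_g)
  aligned <- apply_fit(ca_s, fit)
  d2 <- rowSums((aligned - ca_g)^2)
  vapply(elements, function(res) sqrt(mean(d2[res + 1L])), 0)
}

## Elements in the subtree rooted at `node` (the distal set of the edge
## parent -> node).
tree_subtree <- function(tree, node) {
  ne <- length(tree$parent)
  out <- node
  added <- TRUE
  while (added) {
    added <- FALSE
    for (v in seq_len(ne)) {
      if (!is.na(tree$parent[v]) && tree$parent[v] %in% out && !(v %in% out)) {
        out <- c(out, v); added <- TRUE
      }
    }
  }
  sort(out)
}

#' Define the loop dihedral degrees of freedom
#'
#' For each spanning-tree edge whose distal subtree intersects the mobile
#' set, the phi and psi angles of the two junction residues plus up to
#' `window - 1` sequential neighbours on each side become degrees of
#' freedom. Each DOF records the distal element set and the precomputed
#' atom rows it moves (the distal elements plus the distal portion of the
#' junction window).
#'
#' @param tree from [build_spanning_tree()].
#' @param mobile integer vector of mobile element ids (the set K), or "all".
#' @param window number of junction residues taken on each side (>= 1).
#' @param structure the `coarse_structure`.
#' @param elements rigid-element ranges.
#' @return list of DOF records (residue, kind, direction, distal element ids,
#'   moved atom rows, axis atom rows, name).
#' @export
define_dofs <- function(tree, mobile, window = 2L, structure, elements) {
  ne <- length(tree$parent)
  n <- n_residues(structure)
  if (identical(mobile, "all")) mobile <- seq_len(ne)
  dofs <- list()
  for (child in seq_len(ne)) {
    if (is.na(tree$parent[child])) next
    distal <- tree_subtree(tree, child)
    if (!any(distal %in% mobile)) next
    jr <- tree$junction[child, ]
    r_lo <- min(jr); r_hi <- max(jr)
    child_res <- elements[[child]]
    direction <- if (r_hi %in% child_res) "down" else "up"
    d_res <- sort(unlist(elements[distal]))
    win <- max(0L, r_lo - (window - 1L)):min(n - 1L, r_hi + (window - 1L))
    for (r in win) {
      for (kind in c("phi", "psi")) {
        moved <- dof_moved_rows(structure, r, kind, direction, d_res, r_lo, r_hi)
        if (length(moved$rows) == 0L) next
        dofs[[length(dofs) + 1L]] <- list(
          residue = r, kind = kind, direction = direction,
          element = child, distal = distal,
          moved_rows = moved$rows, axis = moved$axis,
          name = sprintf("%s_%d.e%d", kind, r, child))
      }
    }
  }
  names(dofs) <- vapply(dofs, `[[`, "", "name")
  dofs
}

## Atom rows moved by rotating (residue r, kind) toward the distal side, and
## the two atom rows spanning the rotation axis.
dof_moved_rows <- function(structure, r, kind, direction, d_res, r_lo, r_hi) {
  idx <- structure$idx
  row_of <- function(res, nm) {
    v <- idx[res + 1L, nm]; v[!is.na(v)]
  }
  if (kind == "phi") {
    axis <- c(idx[r + 1L, "N"], idx[r + 1L, "CA"])
    part_down <- row_of(r, c("CB", "C", "O"))
    part_up <- row_of(r, "N")
  } else {
    axis <- c(idx[r + 1L, "CA"], idx[r + 1L, "C"])
    part_down <- row_of(r, "O")
    part_up <- row_of(r, c("N", "CA", "CB"))
  }
  if (anyNA(axis)) return(list(rows = integer(0), axis = axis))
  if (direction == "down") {
    gap <- if (r < r_lo) (r + 1L):r_lo else integer(0)
    res_moved <- union(d_res[d_res > r], setdiff(gap, d_res))
    rows <- c(part_down, residue_rows(structure, res_moved))
  } else {
    gap <- if (r > r_hi) r_hi:(r - 1L) else integer(0)
    res_moved <- union(d_res[d_res < r], setdiff(gap, d_res))
    rows <- c(part_up, residue_rows(structure, res_moved))
  }
  list(rows = sort(unique(rows)), axis = axis)
}

#' Assemble the full pathway topology for a transition
#'
#' Convenience wrapper that assigns secondary structure, groups residues
#' into rigid elements, builds the element graph and spanning tree, and
#' defines the loop degrees of freedom, returning everything needed to
#' create and move conformations.
#'
#' @param start,goal `coarse_structure` objects of the two end states; they
#'   must share residue content.
#' @param sse optional pre-computed annotation data.frame (see
#'   [assign_sse()]); computed from `start` when NULL.
#' @param header_records optional PDB header lines forwarded to [assign_sse()].
#' @param merge_groups forwarded to [assign_rigid_elements()].
#' @param mobile mobile element ids (the set K) or "all" (default).
#' @param window junction window for [define_dofs()].
#' @return object of class `pathway_topology`.
#' @export
build_topology <- function(start, goal, sse = NULL, header_records = NULL,
                           merge_groups = NULL, mobile = "all", window = 2L) {
  stopifnot(inherits(start, "coarse_structure"),
            inherits(goal, "coarse_structure"))
  if (n_residues(start) != n_residues(goal) ||
      !all(start$aa == goal$aa))
    stop("start and goal structures do not share residue content")
  if (is.null(sse)) sse <- assign_sse(start, header_records)
  elements <- assign_rigid_elements(sse, start, merge_groups)
  graph <- build_graph(elements, start)
  tree <- build_spanning_tree(graph, start, goal, elements)
  ne <- length(elements)
  if (identical(mobile, "all")) mobile <- seq_len(ne)
  mobile <- sort(unique(as.integer(mobile)))
  stopifnot(all(mobile >= 1L & mobile <= ne))
  dofs <- define_dofs(tree, mobile, window, start, elements)
  topo <- list(structure = start, goal_structure = goal, sse = sse,
               elements = elements, element_kind = attr(elements, "kind"),
               graph = graph, tree = tree, mobile = mobile, window = window,
               dofs = dofs, cache = new.env(parent = emptyenv()))
  class(topo) <- "pathway_topology"
  topo
}

#' @export
print.pathway_topology <- function(x, ...) {
  cat(sprintf(paste0("pathway_topology: %d residues, %d rigid elements ",
                     "(root %s), |K| = %d, %d DOFs\n"),
              n_residues(x$structure), length(x$elements),
              paste(x$tree$roots, collapse = ","), length(x$mobile),
              length(x$dofs)))
  invisible(x)
}
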