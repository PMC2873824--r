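## Progress metric: per-element scores from inter-element angles and
## center-of-mass distances relative to the goal, assembled into a feature
## vector whose Euclidean norm measures distance to the goal. The feature
## vector doubles as the low-dimensional projection the planner subdivides.

#' Metric weights
#'
#' `w_angle` multiplies absolute angle differences (radians) and `w_dist`
#' absolute center-of-mass distance differences (Angstrom). The defaults
#' (5 and 1) bring the two terms to the same order of magnitude: angle
#' differences are bounded by pi while domain-scale distance changes are a
#' few Angstrom. `form = "squared"` switches both terms to squared
#' differences.
#'
#' @param w_angle,w_dist non-negative weights.
#' @param form "abs" (default) or "squared".
#' @return list of class `metric_params`.
#' @export
metric_params <- function(w_angle = 5, w_dist = 1,
                          form = c("abs", "squared")) {
  stopifnot(w_angle >= 0, w_dist >= 0)
  out <- list(w_angle = w_angle, w_dist = w_dist, form = match.arg(form))
  class(out) <- "metric_params"
  out
}

#' Representative axis of a rigid element
#'
#' Helices: the principal axis of the element's CA coordinates (largest
#' variance direction), oriented from the N-terminal to the C-terminal half
#' centroid. Sheets, merged and mixed elements: the normal of the
#' least-squares plane (smallest variance direction); its sign is not
#' meaningful, so angles against such axes are folded to [0, pi/2].
#'
#' @param conf a `conformation`.
#' @param element element id.
#' @return unit 3-vector with attribute `oriented` (TRUE for helix axes).
#' @export
element_axis <- function(conf, element) {
  topo <- conf$topology
  res <- topo$elements[[element]]
  rows <- topo$structure$idx[res + 1L, "CA"]
  rows <- rows[!is.na(rows)]
  if (length(rows) < 3L) stop("element axis needs at least 3 CA atoms")
  X <- conf$xyz[rows, , drop = FALSE]
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 0L)
  helix <- topo$element_kind[element] == "helix"
  ax <- if (helix) sv$v[, 1L] else sv$v[, 3L]
  ax <- unit(ax)
  if (helix) {
    half <- ceiling(nrow(X) / 2)
    dirv <- colMeans(X[(nrow(X) - half + 1L):nrow(X), , drop = FALSE]) -
            colMeans(X[seq_len(half), , drop = FALSE])
    if (sum(ax * dirv) < 0) ax <- -ax
  }
  attr(ax, "oriented") <- helix
  ax
}

#' Relative geometry of an element pair
#'
#' @param conf a `conformation`.
#' @param i,j element ids (i != j).
#' @return list with `alpha` (inter-axis angle, radians; folded to
#'   [0, pi/2] when either axis is sign-ambiguous) and `dist`
#'   (center-of-mass distance over retained atoms, Angstrom).
#' @export
pair_geometry <- function(conf, i, j) {
  stopifnot(i != j)
  ai <- element_axis(conf, i)
  aj <- element_axis(conf, j)
  dt <- max(-1, min(1, sum(ai * aj)))
  alpha <- if (attr(ai, "oriented") && attr(aj, "oriented")) acos(dt)
           else acos(abs(dt))
  list(alpha = alpha, dist = vnorm(element_com(conf, i) -
                                   element_com(conf, j)))
}

element_com <- function(conf, element) {
  rows <- residue_rows(conf$topology$structure,
                       conf$topology$elements[[element]])
  colMeans(conf$xyz[rows, , drop = FALSE])
}

## All mobile-pair geometries at once; cached pair table for a conformation
## would not help (coordinates change each move), but goal geometry is
## cached in the topology.
pair_table <- function(conf, mobile) {
  m <- length(mobile)
  alpha <- matrix(0, m, m); dist <- matrix(0, m, m)
  if (m >= 2L) for (a in 1:(m - 1L)) for (b in (a + 1L):m) {
    pg <- pair_geometry(conf, mobile[a], mobile[b])
    alpha[a, b] <- alpha[b, a] <- pg$alpha
    dist[a, b] <- dist[b, a] <- pg$dist
  }
  list(alpha = alpha, dist = dist)
}

goal_pair_table <- function(goal) {
  topo <- goal$topology
  fp <- c(nrow(goal$xyz), sum(goal$xyz), sum(goal$xyz^2))
  hit <- topo$cache[["goal_pairs"]]
  if (!is.null(hit) && isTRUE(all.equal(hit$fp, fp))) return(hit$pt)
  pt <- pair_table(goal, topo$mobile)
  assign("goal_pairs", list(fp = fp, pt = pt), envir = topo$cache)
  pt
}

#' Per-element score against the goal geometry
#'
#' The score of mobile element i sums, over the other mobile elements j,
#' the weighted deviations of the inter-element angle and center-of-mass
#' distance from their values in the goal structure. Zero iff every mobile
#' pair involving i matches the goal geometry.
#'
#' @param conf a `conformation`.
#' @param i a mobile element id.
#' @param goal the goal `conformation` (shared topology).
#' @param params a `metric_params`.
#' @return non-negative scalar.
#' @export
element_score <- function(conf, i, goal, params = metric_params()) {
  fv <- feature_vector(conf, goal, params)
  k <- match(i, conf$topology$mobile)
  if (is.na(k)) stop("element ", i, " is not in the mobile set")
  fv[k]
}

#' Feature vector of a conformation
#'
#' Vector of per-mobile-element scores (fixed element-id order); its
#' Euclidean norm is the conformation's distance to the goal, and it is the
#' projection coordinates used by the planner's subdivision.
#'
#' @inheritParams element_score
#' @return numeric vector of length |K|.
#' @export
feature_vector <- function(conf, goal, params = metric_params()) {
  topo <- conf$topology
  mobile <- topo$mobile
  m <- length(mobile)
  if (m < 2L) {
    warning("fewer than 2 mobile elements: scores are identically zero")
    return(numeric(m))
  }
  pt <- pair_table(conf, mobile)
  gt <- goal_pair_table(goal)
  da <- abs(pt$alpha - gt$alpha)
  dd <- abs(pt$dist - gt$dist)
  if (params$form == "squared") { da <- da^2; dd <- dd^2 }
  contrib <- params$w_angle * da + params$w_dist * dd
  diag(contrib) <- 0
  rowSums(contrib)
}

#' Distance between two conformations
#'
#' Euclidean distance between feature vectors. Against the goal itself this
#' equals the norm of the conformation's feature vector. It is a
#' pseudometric: zero distance does not imply identical coordinates, since
#' only relative element geometry enters.
#'
#' @param c1,c2 `conformation` objects sharing a topology.
#' @inheritParams element_score
#' @return non-negative scalar.
#' @export
conf_distance <- function(c1, c2, goal, params = metric_params()) {
  sqrt(sum((feature_vector(c1, goal, params) -
            feature_vector(c2, goal, params))^2))
}

#' Normalized distance to the goal
#'
#' Distance to the goal on a 0-1 scale where the start conformation is at 1
#' and the goal at 0.
#'
#' @param conf a `conformation`.
#' @param start,goal the transition end states.
#' @inheritParams element_score
#' @return non-negative scalar (can exceed 1 for conformations farther from
#'   the goal than the start).
#' @export
normalized_distance <- function(conf, start, goal,
                                params = metric_params()) {
  d0 <- sqrt(sum(feature_vector(start, goal, params)^2))
  if (d0 <= 0) stop("start and goal coincide under the metric")
  sqrt(sum(feature_vector(conf, goal, params)^2)) / d0
}
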