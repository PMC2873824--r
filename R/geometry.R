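# Low-level 3D geometry shared by the kinematics, metric and analysis code.
# All coordinates are plain numeric matrices (n x 3), units of Angstrom;
# all angles are radians unless a function name says degrees.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Rotation matrix for a right-handed rotation by `theta` about unit axis `u`
## (Rodrigues form).
rotation_matrix <- function(u, theta) {
  u <- unit(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

## Rotate the rows of `xyz` about the axis through `point` with direction `u`.
rotate_about_axis <- function(xyz, point, u, theta) {
  R <- rotation_matrix(u, theta)
  shifted <- sweep(xyz, 2L, point)
  sweep(shifted %*% t(R), 2L, point, `+`)
}

## Signed dihedral angle p1-p2-p3-p4 in (-pi, pi].
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x)
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

## Angle at vertex b of triple (a, b, c), in [0, pi].
bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

## Natural-extension (NeRF) placement: position atom d bonded to c with
## |c-d| = length, angle(b, c, d) = theta, dihedral(a, b, c, d) = chi.
place_atom <- function(a, b, c, length, theta, chi) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-length * cos(theta),
          length * sin(theta) * cos(chi),
          -length * sin(theta) * sin(chi))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Optimal superposition of P onto Q (both n x 3, rows paired) restricted to
## proper rotations. Returns the rotation, translation and the residual RMSD.
kabsch <- function(P, Q) {
  if (!is.matrix(P)) P <- matrix(P, ncol = 3L)
  if (!is.matrix(Q)) Q <- matrix(Q, ncol = 3L)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  if (nrow(P) < 3L) stop("need at least 3 paired points for superposition")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp)
  Q0 <- sweep(Q, 2L, cq)
  H <- crossprod(P0, Q0)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u))) # exclude reflections
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  list(R = R, center_p = cp, center_q = cq, rmsd = rmsd)
}

## Apply a kabsch() fit to arbitrary coordinates.
apply_fit <- function(xyz, fit) {
  sweep(sweep(xyz, 2L, fit$center_p) %*% t(fit$R), 2L, fit$center_q, `+`)
}
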