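# Internal 3D geometry helpers. Coordinates are plain numeric length-3
# vectors or n x 3 matrices; the package-wide unit is nm unless a function
# says otherwise.

.vnorm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) abort("Cannot normalize a zero vector.")
  v / n
}

.cross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Place atom D given A-B-C with bond |CD|, angle B-C-D (deg) and torsion
# A-B-C-D (deg). Natural-extension-reference-frame construction used for
# building backbones from internal coordinates.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(ang), cos(tor) * sin(ang), -sin(tor) * sin(ang))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# dihedral angle a-b-c-d in degrees, in (-180, 180]
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# rotation matrix for angle theta (radians) about unit axis
.rotmat <- function(axis, theta) {
  u <- .unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# rotation matrix taking unit vector `from` onto unit vector `to`
.rot_between <- function(from, to) {
  f <- .unit(from); t <- .unit(to)
  d <- sum(f * t)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # pick any perpendicular axis for the half-turn
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(.cross(f, ref))
    return(.rotmat(axis, pi))
  }
  axis <- .cross(f, t)
  .rotmat(axis, acos(d))
}

# principal axis (largest-variance direction) of an n x 3 point matrix
.principal_axis <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  ev$vectors[, 1]
}

# Kabsch superposition: rotation R and translation t such that
# X %*% R + t approximates Y (both n x 3). Returns list(R, t).
.kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t <- cy - as.numeric(cx %*% R)
  list(R = R, t = t)
}

.apply_rigid <- function(X, R, t = c(0, 0, 0)) {
  sweep(X %*% R, 2, t, `+`)
}
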