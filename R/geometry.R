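## Internal geometry helpers: vectors, rotations, quaternions, Kabsch.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

## Angle (degrees) at vertex `a` between directions a->b and a->c.
angle_deg <- function(a, b, c) {
  u <- b - a; v <- c - a
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

## Rodrigues rotation matrix from a rotation vector (axis * angle, radians).
rotvec_matrix <- function(r) {
  theta <- vnorm(r)
  if (theta < 1e-12) return(diag(3))
  k <- r / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

axis_angle_matrix <- function(axis, angle) rotvec_matrix(unitv(axis) * angle)

## Quaternion (w, x, y, z) utilities. Unit quaternions represent rotations;
## q and -q encode the same rotation (double cover).
quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / vnorm(q)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## Uniform random unit quaternions (Shoemake's method); n x 4 matrix.
random_quats <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

## Orientation of a water as a unit quaternion: body frame has O at the
## origin, the H-O-H bisector along +z and the H1->H2 axis along -x
## (i.e. H1 sits at +x). Rows of oh1, oh2 are lab-frame H - O vectors.
water_quats <- function(oh1, oh2) {
  n <- nrow(oh1)
  out <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    b1 <- unitv(oh1[i, ]); b2 <- unitv(oh2[i, ])
    z <- unitv(b1 + b2)
    xr <- b1 - b2
    x <- unitv(xr - sum(xr * z) * z)
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    out[i, ] <- quat_from_matrix(cbind(x, y, z))
  }
  out
}

## Least-squares rigid superposition (Kabsch): rotation R and translation t
## such that R %*% t(P) + t best fits Q (both n x 3, n >= 1).
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cq - as.vector(R %*% cp)
  fitted <- t(R %*% t(P)) + matrix(t_vec, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t_vec, rmsd = rmsd, fitted = fitted)
}

apply_rigid <- function(X, R, t_vec) {
  t(R %*% t(X)) + matrix(t_vec, nrow(X), 3, byrow = TRUE)
}

## Best-fit plane unit normal through points (n x 3, n >= 3).
plane_normal <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  unitv(sv$v[, 3])
}

## Lennard-Jones (12-6, Lorentz-Berthelot mixing) + Coulomb energy between
## two atom sets. xyz: n x 3 matrices; q, sig, eps: per-atom vectors.
## Returns total cross energy in kcal/mol.
pair_energy <- function(xyz1, q1, sig1, eps1, xyz2, q2, sig2, eps2) {
  if (nrow(xyz1) == 0L || nrow(xyz2) == 0L) return(0)
  dx <- outer(xyz1[, 1], xyz2[, 1], "-")
  dy <- outer(xyz1[, 2], xyz2[, 2], "-")
  dz <- outer(xyz1[, 3], xyz2[, 3], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  r[r < 1e-9] <- 1e-9
  e_coul <- .coulomb_k * outer(q1, q2) / r
  epsij <- sqrt(outer(eps1, eps2))
  lj <- 0 * r
  nz <- epsij > 0
  if (any(nz)) {
    sigij <- outer(sig1, sig2, "+") / 2
    sr6 <- (sigij[nz] / r[nz])^6
    lj[nz] <- 4 * epsij[nz] * (sr6^2 - sr6)
  }
  sum(e_coul) + sum(lj)
}
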