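## Pairwise force decomposition of classical force-field terms.
##
## Every many-body gradient (angle, dihedral) is re-expressed as central
## forces between atom pairs: the force set {F_a} of one term instance has
## zero net force and zero net torque, so it is exactly representable as
## scalar magnitudes on the pair separation axes (3 pairs for an angle,
## 6 for a dihedral). The magnitudes are recovered by a minimum-norm
## least-squares solve; the residual is checked and a degenerate-geometry
## error raised where the representation breaks down (collinear arms).
## This is what makes per-pair virial attribution (and hence a symmetric
## per-atom stress) possible for non-central terms.

#' Pair geometry between two atoms
#'
#' @param ri,rj positions of atoms i and j (length-3, nm)
#' @param box optional orthorhombic box edges for minimum-image convention
#' @return list with `r_ij` (vector from j to i, nm) and `dist` (nm)
#' @export
pair_geometry <- function(ri, rj, box = NULL) {
  d <- as.numeric(ri) - as.numeric(rj)
  if (!is.null(box)) d <- d - box * round(d / box)
  list(r_ij = d, dist = sqrt(sum(d * d)))
}

.pf <- function(i, j, f, term) {
  data.frame(i = as.integer(i), j = as.integer(j),
             fx = f[1], fy = f[2], fz = f[3],
             term = term, stringsAsFactors = FALSE)
}

.degenerate <- function(term, what) {
  stop(sprintf("degenerate geometry in %s term: %s", term, what), call. = FALSE)
}

#' Pairwise force of a harmonic bond
#'
#' V = 1/2 kb (b - b0)^2. The force on atom i is along the pair axis and
#' attractive when the bond is stretched.
#'
#' @param geom a [pair_geometry()] for atoms (i, j)
#' @param kb force constant (kJ/mol/nm^2)
#' @param b0 equilibrium length (nm)
#' @param i,j atom indices to record
#' @return one-row data.frame (i, j, fx, fy, fz, term): force on i (kJ/mol/nm)
#' @export
bond_pair_force <- function(geom, kb, b0, i = 1L, j = 2L) {
  if (geom$dist <= 0) .degenerate("bond", "coincident atoms")
  e <- geom$r_ij / geom$dist
  .pf(i, j, -kb * (geom$dist - b0) * e, "bond")
}

#' Pairwise Lennard-Jones force
#'
#' V = 4 eps ((sigma/r)^12 - (sigma/r)^6); magnitude
#' scale * (24 eps / r) * (2 (sigma/r)^12 - (sigma/r)^6), positive =
#' repulsive (along +e_ij on atom i).
#'
#' @param geom a [pair_geometry()]
#' @param sigma_ij,epsilon_ij combined LJ parameters (nm, kJ/mol)
#' @param scale scale factor (1, or the 1-4 LJ scale)
#' @param i,j atom indices to record
#' @return one-row pair-force data.frame
#' @export
lj_pair_force <- function(geom, sigma_ij, epsilon_ij, scale = 1, i = 1L, j = 2L) {
  r <- geom$dist
  if (r <= 0) .degenerate("vdw", "coincident atoms")
  sr6 <- (sigma_ij / r)^6
  mag <- scale * (24 * epsilon_ij / r) * (2 * sr6 * sr6 - sr6)
  .pf(i, j, mag * geom$r_ij / r, "vdw")
}

#' Pairwise Coulomb force
#'
#' V = f q_i q_j / r with f = 138.935458 kJ mol^-1 nm e^-2; repulsive for
#' like charges.
#'
#' @param geom a [pair_geometry()]
#' @param q_i,q_j charges (e)
#' @param scale scale factor (1, or the 1-4 Coulomb scale)
#' @param i,j atom indices to record
#' @return one-row pair-force data.frame
#' @export
coulomb_pair_force <- function(geom, q_i, q_j, scale = 1, i = 1L, j = 2L) {
  r <- geom$dist
  if (r <= 0) .degenerate("coulomb", "coincident atoms")
  mag <- scale * .COULOMB_K * q_i * q_j / r^2
  .pf(i, j, mag * geom$r_ij / r, "coulomb")
}

## --- analytic gradients of the many-body terms ------------------------------

# angle theta at vertex rj; returns theta and dtheta/dr for each atom
.angle_geometry <- function(ri, rj, rk) {
  u <- ri - rj; v <- rk - rj
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu <= 0 || nv <= 0) .degenerate("angle", "zero-length arm")
  ct <- sum(u * v) / (nu * nv)
  ct <- max(-1, min(1, ct))
  st <- sqrt(max(0, 1 - ct * ct))
  if (st < 1e-12) .degenerate("angle", "collinear arms (sin(theta) ~ 0)")
  theta <- acos(ct)
  dti <- (ct * u / nu^2 - v / (nu * nv)) / st
  dtk <- (ct * v / nv^2 - u / (nu * nv)) / st
  list(theta = theta, d_i = dti, d_j = -(dti + dtk), d_k = dtk)
}

# torsion phi over ri-rj-rk-rl; returns phi and dphi/dr for each atom
.dihedral_geometry <- function(ri, rj, rk, rl) {
  b1 <- rj - ri; b2 <- rk - rj; b3 <- rl - rk
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  n1sq <- sum(n1 * n1); n2sq <- sum(n2 * n2)
  nb2 <- sqrt(sum(b2 * b2))
  if (nb2 <= 0) .degenerate("dihedral", "zero-length central bond")
  if (n1sq < 1e-20 || n2sq < 1e-20)
    .degenerate("dihedral", "three collinear consecutive atoms")
  phi <- atan2(sum(.cross(n1, n2) * b2) / nb2, sum(n1 * n2))
  d_i <- -nb2 / n1sq * n1
  d_l <- nb2 / n2sq * n2
  s <- sum(b1 * b2) / nb2^2
  t <- sum(b3 * b2) / nb2^2
  d_j <- -(1 + s) * d_i + t * d_l
  d_k <- s * d_i - (1 + t) * d_l
  list(phi = phi, d_i = d_i, d_j = d_j, d_k = d_k, d_l = d_l)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Exact central-force representation of a zero-net-force, zero-net-torque
# force set. coords: m x 3; pairs: p x 2 (rows index coords); forces: m x 3.
# Returns scalar magnitudes s (positive = repulsive) so that
#   F_a = sum_p s_p * (+/-) e_p ,  e_p = (r_a - r_b)/|r_a - r_b|.
.central_decomposition <- function(coords, pairs, forces, term) {
  m <- nrow(coords); p <- nrow(pairs)
  A <- matrix(0, 3 * m, p)
  for (q in seq_len(p)) {
    a <- pairs[q, 1]; b <- pairs[q, 2]
    d <- coords[a, ] - coords[b, ]
    nd <- sqrt(sum(d * d))
    if (nd <= 0) .degenerate(term, "coincident atoms in pair decomposition")
    e <- d / nd
    A[(3 * a - 2):(3 * a), q] <- e
    A[(3 * b - 2):(3 * b), q] <- -e
  }
  fvec <- as.numeric(t(forces))
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  s <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% fvec) / sv$d[pos])
  resid <- sqrt(sum((A %*% s - fvec)^2))
  if (resid > 1e-8 * max(1, sqrt(sum(fvec^2))))
    .degenerate(term, "force set not representable by central pair forces")
  as.numeric(s)
}

#' Pairwise decomposition of a harmonic angle term
#'
#' V = 1/2 ktheta (theta - theta0)^2 over atoms (i, j, k) with vertex j.
#' The analytic per-atom gradient is decomposed into central forces on the
#' pairs i-j, k-j and i-k; per-atom sums of the returned records reproduce
#' -grad V exactly.
#'
#' @param ri,rj,rk positions (nm); j is the vertex
#' @param ktheta force constant (kJ/mol/rad^2)
#' @param theta0 equilibrium angle (rad)
#' @param idx integer atom indices to record for (i, j, k)
#' @return 3-row pair-force data.frame (force on the first atom of each pair)
#' @export
angle_pairwise_forces <- function(ri, rj, rk, ktheta, theta0, idx = 1:3) {
  g <- .angle_geometry(ri, rj, rk)
  dv <- ktheta * (g$theta - theta0)
  forces <- rbind(-dv * g$d_i, -dv * g$d_j, -dv * g$d_k)
  coords <- rbind(ri, rj, rk)
  pairs <- rbind(c(1L, 2L), c(3L, 2L), c(1L, 3L))
  s <- .central_decomposition(coords, pairs, forces, "angle")
  do.call(rbind, lapply(seq_len(3), function(q) {
    a <- pairs[q, 1]; b <- pairs[q, 2]
    d <- coords[a, ] - coords[b, ]
    .pf(idx[a], idx[b], s[q] * d / sqrt(sum(d * d)), "angle")
  }))
}

#' Pairwise decomposition of a periodic dihedral term
#'
#' V = kphi (1 + cos(mult * phi - phase)) over atoms (i, j, k, l). Only
#' phase values 0 or pi are supported (for other phases the pairwise stress
#' decomposition of this functional form is singular at certain torsion
#' angles); the gradient is decomposed into central forces on all six atom
#' pairs of the quadruple. Forces are finite for all phi, including 0 and
#' pi.
#'
#' @param ri,rj,rk,rl positions (nm)
#' @param kphi barrier parameter (kJ/mol)
#' @param mult integer multiplicity (>= 1)
#' @param phase phase angle, must be 0 or pi (rad)
#' @param idx integer atom indices to record for (i, j, k, l)
#' @return 6-row pair-force data.frame
#' @export
dihedral_pairwise_forces <- function(ri, rj, rk, rl, kphi, mult, phase, idx = 1:4) {
  if (min(abs(phase), abs(phase - pi), abs(phase + pi)) > 1e-9)
    stop("unsupported dihedral phase ", phase,
         ": pairwise stress decomposition requires phase 0 or pi", call. = FALSE)
  g <- .dihedral_geometry(ri, rj, rk, rl)
  dv <- -kphi * mult * sin(mult * g$phi - phase)
  forces <- rbind(-dv * g$d_i, -dv * g$d_j, -dv * g$d_k, -dv * g$d_l)
  coords <- rbind(ri, rj, rk, rl)
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                 c(2L, 3L), c(2L, 4L), c(3L, 4L))
  s <- .central_decomposition(coords, pairs, forces, "dihedral")
  do.call(rbind, lapply(seq_len(6), function(q) {
    a <- pairs[q, 1]; b <- pairs[q, 2]
    d <- coords[a, ] - coords[b, ]
    .pf(idx[a], idx[b], s[q] * d / sqrt(sum(d * d)), "dihedral")
  }))
}

#' Sum pair-force records into per-atom force vectors
#'
#' Each record carries the force on atom `i`; Newton's third law supplies
#' the opposite force on atom `j`.
#'
#' @param pf pair-force data.frame (rows from the `*_pair_force*` functions)
#' @param n number of atoms
#' @return n x 3 matrix of per-atom forces (kJ/mol/nm)
#' @export
sum_pair_forces <- function(pf, n) {
  out <- matrix(0, n, 3)
  if (is.null(pf) || nrow(pf) == 0) return(out)
  f <- as.matrix(pf[, c("fx", "fy", "fz")])
  for (q in seq_len(nrow(pf))) {
    out[pf$i[q], ] <- out[pf$i[q], ] + f[q, ]
    out[pf$j[q], ] <- out[pf$j[q], ] - f[q, ]
  }
  out
}
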