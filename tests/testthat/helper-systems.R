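# shared helpers: relative error, rigid motions, small random systems

relerr <- function(a, b, floor = 1) max(abs(a - b)) / max(floor, max(abs(b)))

rigid_rotate <- function(x, angles = c(0.3, -0.7, 1.1), shift = c(1, -2, 0.5)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  sweep(x %*% t(Rz %*% Ry %*% Rx), 2, -shift)
}

# one atom row for ad-hoc topologies
atom_df <- function(n, mass = 12.011, charge = 0, sigma = 0.34, epsilon = 0.36,
                    resid = NULL, gb_radius = NA_real_, gb_screen = NA_real_) {
  data.frame(name = sprintf("A%d", seq_len(n)),
             resid = if (is.null(resid)) seq_len(n) else resid,
             resname = "MOL",
             mass = rep_len(mass, n), charge = rep_len(charge, n),
             sigma = rep_len(sigma, n), epsilon = rep_len(epsilon, n),
             gb_radius = rep_len(gb_radius, n),
             gb_screen = rep_len(gb_screen, n),
             stringsAsFactors = FALSE)
}

# random GB-parameterized charged cluster for gradient checks
random_gb_system <- function(n = 4) {
  x <- matrix(stats::runif(3 * n, 0, 0.45), n, 3)
  # keep atoms from overlapping
  for (it in 1:100) {
    d <- as.matrix(stats::dist(x))
    diag(d) <- 1
    bad <- which(d < 0.12, arr.ind = TRUE)
    if (nrow(bad) == 0) break
    i <- bad[1, 1]
    x[i, ] <- stats::runif(3, 0, 0.45)
  }
  atoms <- atom_df(n, charge = stats::runif(n, -0.8, 0.8),
                   gb_radius = stats::runif(n, 0.12, 0.2),
                   gb_screen = stats::runif(n, 0.7, 0.9))
  list(x = x, atoms = atoms, top = fftop(atoms))
}

# independent brute-force OBC/Still reference used to validate the module;
# written directly from the closed-form expressions, no shared code paths
# with compute_born_radii()/gb_energy() internals
oracle_gb <- function(x, rho, screen, q, p = gb_params()) {
  n <- nrow(x)
  rt <- rho - p$offset
  s <- screen * rt
  I <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (r > p$cutoff || rt[i] >= r + s[j]) next
    U <- r + s[j]
    L <- max(rt[i], abs(r - s[j]))
    term <- 1 / L - 1 / U + r / 4 * (1 / U^2 - 1 / L^2) +
      1 / (2 * r) * log(L / U) + s[j]^2 / (4 * r) * (1 / L^2 - 1 / U^2)
    if (rt[i] < s[j] - r) term <- term + 2 * (1 / rt[i] - 1 / L)
    I[i] <- I[i] + term
  }
  psi <- 0.5 * I * rt
  R <- 1 / (1 / rt - tanh(p$alpha * psi - p$beta * psi^2 + p$gamma * psi^3) / rho)
  C <- 138.935458 * (1 / p$dielectric_solute - 1 / p$dielectric_solvent)
  e <- sum(q^2 / (2 * R))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r2 <- sum((x[i, ] - x[j, ])^2)
    if (sqrt(r2) > p$cutoff) next
    fgb <- sqrt(r2 + R[i] * R[j] * exp(-r2 / (4 * R[i] * R[j])))
    e <- e + q[i] * q[j] / fgb
  }
  list(R = R, energy = -C * e)
}
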