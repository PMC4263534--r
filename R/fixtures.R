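## Test-input generators: analytic micro-structures (1-5 atoms) with known
## stress signatures, a finite-difference force oracle, a graphene
## ribbon/nanotube builder with embedded aromatic-carbon (GAFF "ca")
## parameters, Maxwell-Boltzmann thermalization, velocity pulses, a
## velocity-Verlet NVE driver, and wavefront-speed measurement for
## stress-wave experiments. Everything is generated in code; no external
## files are needed.

.atom_row <- function(name = "C", resid = 1L, resname = "MOL", mass = 12.011,
                      charge = 0, sigma = 0.34, epsilon = 0.36,
                      gb_radius = NA_real_, gb_screen = NA_real_) {
  data.frame(name = name, resid = resid, resname = resname, mass = mass,
             charge = charge, sigma = sigma, epsilon = epsilon,
             gb_radius = gb_radius, gb_screen = gb_screen,
             stringsAsFactors = FALSE)
}

#' Catalog of analytic validation structures
#'
#' Deterministic, seed-free micro-systems (1-5 atoms) small enough that the
#' expected stresses can be evaluated by hand. Each entry holds a topology,
#' coordinates, and a manifest naming the stress terms expected to be zero
#' and nonzero at those coordinates.
#'
#' @return named list of entries: `top`, `x`, and `expect`
#'   (list of `zero` / `nonzero` term-name vectors)
#' @export
build_test_structures <- function() {
  out <- list()

  # diatomic at equilibrium: every term zero
  top <- fftop(rbind(.atom_row(charge = 0, epsilon = 0),
                     .atom_row(charge = 0, epsilon = 0)),
               bonds = data.frame(i = 1, j = 2, kb = 1000, b0 = 0.1),
               exclusions = data.frame(i = 1, j = 2))
  out$bond_eq <- list(top = top, x = rbind(c(0, 0, 0), c(0.1, 0, 0)),
                      expect = list(zero = .STRESS_TERMS, nonzero = character(0)))

  # stretched diatomic: the worked bond-stress example
  out$bond_stretched <- list(top = top, x = rbind(c(0, 0, 0), c(0.12, 0, 0)),
                             expect = list(zero = setdiff(.STRESS_TERMS, "bond"),
                                           nonzero = "bond"))

  # bent triatomic (water-like geometry, bent away from theta0)
  top <- fftop(rbind(.atom_row(epsilon = 0), .atom_row(epsilon = 0),
                     .atom_row(epsilon = 0)),
               bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                  kb = 1000, b0 = 0.1),
               angles = data.frame(i = 1, j = 2, k = 3, ktheta = 400,
                                   theta0 = 104.5 * pi / 180),
               exclusions = data.frame(i = c(1, 2, 1), j = c(2, 3, 3)))
  th <- 120 * pi / 180
  out$angle_bent <- list(
    top = top,
    x = rbind(c(0.1, 0, 0), c(0, 0, 0),
              0.1 * c(cos(th), sin(th), 0)),
    expect = list(zero = setdiff(.STRESS_TERMS, "angle"), nonzero = "angle"))

  # 4-atom torsion at a stationary point (n=3, phase 0, phi = 60 deg)
  dtop <- function(kphi, mult, phase) fftop(
    do.call(rbind, rep(list(.atom_row(epsilon = 0)), 4)),
    bonds = data.frame(i = 1:3, j = 2:4, kb = 1000, b0 = 0.15),
    angles = data.frame(i = c(1, 2), j = c(2, 3), k = c(3, 4),
                        ktheta = 0, theta0 = 110 * pi / 180),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, kphi = kphi,
                           mult = mult, phase = phase),
    exclusions = data.frame(i = c(1, 2, 3, 1, 2), j = c(2, 3, 4, 3, 4)),
    pairs14 = data.frame(i = 1, j = 4, qscale = 1, ljscale = 1))
  tors_x <- function(phi) {
    # backbone with bond length 0.15 nm, angles 110 deg, torsion phi
    ang <- 110 * pi / 180
    p1 <- c(0.15 * cos(pi - ang), 0.15 * sin(pi - ang), 0)
    p2 <- c(0, 0, 0)
    p3 <- c(0.15, 0, 0)
    d <- c(cos(pi - ang), sin(pi - ang) * cos(phi), sin(pi - ang) * sin(phi))
    rbind(p1, p2, p3, p3 - 0.15 * d)
  }
  out$torsion_stationary <- list(
    top = dtop(10, 3, 0), x = tors_x(pi / 3),
    expect = list(zero = .STRESS_TERMS, nonzero = character(0)))
  out$torsion_generic <- list(
    top = dtop(10, 3, 0), x = tors_x(0.4),
    expect = list(zero = setdiff(.STRESS_TERMS, "dihedral"),
                  nonzero = "dihedral"))

  # charged pair (no LJ, no bond)
  top <- fftop(rbind(.atom_row(charge = 1, epsilon = 0),
                     .atom_row(charge = -1, epsilon = 0)))
  out$charged_pair <- list(top = top, x = rbind(c(0, 0, 0), c(0.3, 0, 0)),
                           expect = list(zero = setdiff(.STRESS_TERMS, "coulomb"),
                                         nonzero = "coulomb"))

  # LJ pair at the potential minimum and off it
  top <- fftop(rbind(.atom_row(), .atom_row()))
  out$lj_pair_min <- list(top = top,
                          x = rbind(c(0, 0, 0), c(2^(1 / 6) * 0.34, 0, 0)),
                          expect = list(zero = .STRESS_TERMS, nonzero = character(0)))
  out$lj_pair_off <- list(top = top, x = rbind(c(0, 0, 0), c(0.3, 0, 0)),
                          expect = list(zero = setdiff(.STRESS_TERMS, "vdw"),
                                        nonzero = "vdw"))

  # 5-atom combined system with charges, LJ and GB parameters
  atoms5 <- rbind(
    .atom_row(name = "C1", charge = 0.3, gb_radius = 0.17, gb_screen = 0.72),
    .atom_row(name = "O1", mass = 15.999, charge = -0.5, sigma = 0.30,
              epsilon = 0.65, gb_radius = 0.15, gb_screen = 0.85),
    .atom_row(name = "C2", charge = 0.1, gb_radius = 0.17, gb_screen = 0.72),
    .atom_row(name = "H1", resid = 2L, mass = 1.008, charge = 0.25,
              sigma = 0.25, epsilon = 0.066, gb_radius = 0.12, gb_screen = 0.85),
    .atom_row(name = "H2", resid = 2L, mass = 1.008, charge = -0.15,
              sigma = 0.25, epsilon = 0.066, gb_radius = 0.12, gb_screen = 0.85))
  top5 <- fftop(
    atoms5,
    bonds = data.frame(i = c(1, 2, 3), j = c(2, 3, 4),
                       kb = c(25000, 30000, 28000), b0 = c(0.143, 0.141, 0.109)),
    angles = data.frame(i = c(1, 2), j = c(2, 3), k = c(3, 4),
                        ktheta = c(450, 400),
                        theta0 = c(109.5, 108) * pi / 180),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, kphi = 4.6,
                           mult = 3, phase = 0),
    exclusions = data.frame(i = c(1, 2, 3, 1, 2), j = c(2, 3, 4, 3, 4)),
    pairs14 = data.frame(i = 1, j = 4, qscale = 1 / 1.2, ljscale = 0.5))
  x5 <- rbind(c(0.000, 0.010, 0.00),
              c(0.140, 0.000, 0.02),
              c(0.210, 0.120, 0.00),
              c(0.330, 0.130, 0.09),
              c(0.120, 0.260, 0.15))
  out$combined5 <- list(top = top5, x = x5,
                        expect = list(zero = "kinetic",
                                      nonzero = c("bond", "angle", "dihedral",
                                                  "coulomb", "vdw", "gb")))
  out
}

#' Finite-difference force oracle
#'
#' Central differences of the summed term energies with respect to each
#' coordinate; deliberately independent of the pairwise force
#' decomposition it validates.
#'
#' @param top an `fftop`
#' @param x N x 3 coordinates (nm)
#' @param terms term subset to include (default all potential terms)
#' @param step central-difference step (nm)
#' @param box,cutoff,gb forwarded to [term_energies()]
#' @return N x 3 matrix of per-atom forces (kJ/mol/nm)
#' @export
numerical_force_oracle <- function(top, x, terms = c("bond", "angle", "dihedral",
                                                     "coulomb", "vdw", "gb"),
                                   step = 1e-6, box = NULL, cutoff = Inf,
                                   gb = gb_params()) {
  x <- as.matrix(x)
  e_of <- function(xx) {
    e <- sum(term_energies(top, xx, box = box, cutoff = cutoff, gb = gb,
                           terms = terms))
    if (!is.finite(e)) stop("oracle failure: non-finite energy at displaced point",
                            call. = FALSE)
    e
  }
  f <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) {
    for (k in 1:3) {
      xp <- x; xp[i, k] <- xp[i, k] + step
      xm <- x; xm[i, k] <- xm[i, k] - step
      f[i, k] <- -(e_of(xp) - e_of(xm)) / (2 * step)
    }
  }
  f
}

## ---------------------------------------------------------------------------
## Graphene builder

#' Graphene lattice specification
#'
#' Embedded bonded/nonbonded constants for aromatic sp2 carbon (GAFF 1.4
#' "ca"), converted to the internal V = 1/2 k (b-b0)^2 conventions; all
#' partial charges are zero.
#'
#' @param edge_type `"armchair"` or `"zigzag"`: which edge geometry runs
#'   along the x (length) direction
#' @param width,length sheet dimensions (nm)
#' @param bond_length aromatic C-C bond (nm, default 0.1387)
#' @param kb,b0,ktheta,theta0,kphi,mult,phase bonded parameters
#' @param sigma,epsilon LJ parameters (nm, kJ/mol)
#' @param mass atomic mass (amu)
#' @param qscale14,ljscale14 1-4 scale factors (AMBER conventions)
#' @return list of class `lattice_spec`
#' @export
graphene_spec <- function(edge_type = c("armchair", "zigzag"),
                          width = 4, length = 4, bond_length = 0.1387,
                          kb = 2 * 478.4 * 418.4, b0 = bond_length,
                          ktheta = 2 * 67.18 * 4.184,
                          theta0 = 120.02 * pi / 180,
                          kphi = 3.625 * 4.184, mult = 2L, phase = pi,
                          sigma = 0.3399669508, epsilon = 0.086 * 4.184,
                          mass = 12.011, qscale14 = 1 / 1.2, ljscale14 = 0.5) {
  edge_type <- match.arg(edge_type)
  stopifnot(width > 0, length > 0, bond_length > 0)
  structure(as.list(environment()), class = "lattice_spec")
}

# honeycomb points in the base orientation (zigzag rows along x):
# triangular lattice a1=(sqrt(3) a, 0), a2=(sqrt(3)/2 a, 3/2 a),
# basis (0,0) and (0, a)
.honeycomb_points <- function(a, width, height) {
  a1 <- c(sqrt(3) * a, 0)
  a2 <- c(sqrt(3) / 2 * a, 1.5 * a)
  imax <- ceiling(width / a1[1]) + 3
  jmax <- ceiling(height / a2[2]) + 3
  pts <- list()
  for (j in seq(-2, jmax)) {
    for (i in seq(-2 - ceiling(j / 2), imax)) {
      base <- i * a1 + j * a2
      pts[[length(pts) + 1L]] <- rbind(base, base + c(0, a))
    }
  }
  m <- do.call(rbind, pts)
  m <- m[m[, 1] >= -1e-9 & m[, 1] <= width + 1e-9 &
           m[, 2] >= -1e-9 & m[, 2] <= height + 1e-9, , drop = FALSE]
  m[order(round(m[, 2] / a * 4), round(m[, 1] / a * 4)), , drop = FALSE]
}

# connectivity-derived bonded terms + exclusions/1-4 for a carbon framework
.carbon_topology <- function(xy3, spec, bond_pairs) {
  nb <- vector("list", nrow(xy3))
  for (q in seq_len(nrow(bond_pairs))) {
    i <- bond_pairs[q, 1]; j <- bond_pairs[q, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  angles <- list()
  for (j in seq_along(nb)) {
    nbs <- sort(nb[[j]])
    if (length(nbs) >= 2) {
      cmb <- utils::combn(nbs, 2)
      for (c1 in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- c(cmb[1, c1], j, cmb[2, c1])
    }
  }
  dihedrals <- list()
  for (q in seq_len(nrow(bond_pairs))) {
    j <- bond_pairs[q, 1]; k <- bond_pairs[q, 2]
    for (i in setdiff(nb[[j]], k))
      for (l in setdiff(nb[[k]], j))
        if (i != l) dihedrals[[length(dihedrals) + 1L]] <- c(i, j, k, l)
  }
  ang <- if (length(angles) > 0) do.call(rbind, angles) else matrix(0, 0, 3)
  dih <- if (length(dihedrals) > 0) do.call(rbind, dihedrals) else matrix(0, 0, 4)
  pkey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  k12 <- pkey(bond_pairs[, 1], bond_pairs[, 2])
  k13 <- if (nrow(ang) > 0) pkey(ang[, 1], ang[, 3]) else character(0)
  k14 <- if (nrow(dih) > 0) pkey(dih[, 1], dih[, 4]) else character(0)
  excl_keys <- unique(c(k12, k13))
  p14_keys <- setdiff(unique(k14), excl_keys)
  unkey <- function(keys) {
    if (length(keys) == 0) return(matrix(0, 0, 2))
    do.call(rbind, lapply(strsplit(keys, " "), as.numeric))
  }
  excl <- unkey(excl_keys)
  p14 <- unkey(p14_keys)
  atoms <- .atom_row()[rep(1, nrow(xy3)), ]
  atoms$name <- "CA"
  atoms$resname <- "GRA"
  atoms$resid <- seq_len(nrow(xy3))   # one residue per atom (nanomaterial)
  atoms$mass <- spec$mass
  atoms$charge <- 0
  atoms$sigma <- spec$sigma
  atoms$epsilon <- spec$epsilon
  rownames(atoms) <- NULL
  fftop(atoms,
        bonds = data.frame(i = bond_pairs[, 1], j = bond_pairs[, 2],
                           kb = spec$kb, b0 = spec$b0),
        angles = if (nrow(ang) > 0)
          data.frame(i = ang[, 1], j = ang[, 2], k = ang[, 3],
                     ktheta = spec$ktheta, theta0 = spec$theta0)
          else NULL,
        dihedrals = if (nrow(dih) > 0)
          data.frame(i = dih[, 1], j = dih[, 2], k = dih[, 3], l = dih[, 4],
                     kphi = spec$kphi, mult = spec$mult, phase = spec$phase)
          else NULL,
        pairs14 = if (nrow(p14) > 0)
          data.frame(i = p14[, 1], j = p14[, 2], qscale = spec$qscale14,
                     ljscale = spec$ljscale14)
          else NULL,
        exclusions = if (nrow(excl) > 0)
          data.frame(i = excl[, 1], j = excl[, 2]) else NULL)
}

#' Build a graphene ribbon
#'
#' Honeycomb lattice cropped to `length` x `width` (nm) in the xy plane,
#' with bonds, angles, dihedrals, exclusions and 1-4 pairs enumerated from
#' connectivity; dangling (singly bonded) edge atoms are pruned so every
#' atom is at least 2-coordinated and every interior atom 3-coordinated.
#'
#' @param spec a [graphene_spec()]
#' @return list of class `mini_md`: `top`, `x` (N x 3 nm), `v` (zeros)
#' @export
build_graphene <- function(spec = graphene_spec()) {
  a <- spec$bond_length
  # base orientation: zigzag edges along x. For armchair edges along x,
  # build with the roles of the axes swapped, then transpose coordinates.
  if (spec$edge_type == "zigzag") {
    xy <- .honeycomb_points(a, spec$length, spec$width)
  } else {
    xy <- .honeycomb_points(a, spec$width, spec$length)
    xy <- xy[, c(2, 1)]
  }
  if (nrow(xy) < 8)
    stop("sheet dimensions too small: need at least 2 unit cells each way",
         call. = FALSE)
  # prune dangling atoms iteratively, then rebuild bonds
  repeat {
    bp <- .cpp_nb_pairs(cbind(xy, 0), 1.2 * a, numeric(0), 1e9)
    deg <- tabulate(c(bp[, 1], bp[, 2]), nbins = nrow(xy))
    drop <- which(deg < 2)
    if (length(drop) == 0) break
    xy <- xy[-drop, , drop = FALSE]
    if (nrow(xy) < 8)
      stop("sheet dimensions too small after pruning dangling atoms",
           call. = FALSE)
  }
  x3 <- cbind(xy, 0)
  colnames(x3) <- NULL
  top <- .carbon_topology(x3, spec, bp)
  structure(list(top = top, x = x3, v = matrix(0, nrow(x3), 3),
                 restraint_k = 0, restraint_ref = NULL),
            class = "mini_md")
}

#' Build a graphene nanotube
#'
#' The sheet is periodic along its circumference (x of the flat
#' construction): connectivity is computed with a periodic x distance, so
#' there are no edge atoms along the wrapped direction, then the strip is
#' rolled onto a cylinder with axis along y.
#'
#' @param spec a [graphene_spec()]; `width` is interpreted as the target
#'   circumference and snapped to a whole number of lattice periods
#' @return list of class `mini_md` (cylinder axis along y)
#' @export
build_nanotube <- function(spec = graphene_spec()) {
  a <- spec$bond_length
  period <- if (spec$edge_type == "zigzag") sqrt(3) * a else 3 * a
  ncell <- max(3, round(spec$width / period))
  C <- ncell * period
  if (spec$edge_type == "zigzag") {
    xy <- .honeycomb_points(a, C, spec$length)
  } else {
    xy <- .honeycomb_points(a, spec$length, C)
    xy <- xy[, c(2, 1)]
  }
  # keep [0, C) along x (wrap duplicates out)
  xy <- xy[xy[, 1] < C - 1e-6, , drop = FALSE]
  # periodic connectivity in x
  n <- nrow(xy)
  bp <- list()
  for (i in seq_len(n - 1)) {
    dx <- abs(xy[(i + 1):n, 1] - xy[i, 1])
    dx <- pmin(dx, C - dx)
    dy <- xy[(i + 1):n, 2] - xy[i, 2]
    hit <- which(dx * dx + dy * dy < (1.2 * a)^2)
    for (h in hit) bp[[length(bp) + 1L]] <- c(i, i + h)
  }
  bp <- do.call(rbind, bp)
  # prune dangling atoms at the open (y) ends
  repeat {
    deg <- tabulate(c(bp[, 1], bp[, 2]), nbins = n)
    drop <- which(deg < 2)
    if (length(drop) == 0) break
    keep <- setdiff(seq_len(n), drop)
    remap <- match(seq_len(n), keep)
    xy <- xy[keep, , drop = FALSE]
    bp <- bp[bp[, 1] %in% keep & bp[, 2] %in% keep, , drop = FALSE]
    bp <- cbind(remap[bp[, 1]], remap[bp[, 2]])
    n <- nrow(xy)
  }
  R <- C / (2 * pi)
  theta <- 2 * pi * xy[, 1] / C
  x3 <- cbind(R * cos(theta), xy[, 2], R * sin(theta))
  top <- .carbon_topology(x3, spec, bp)
  structure(list(top = top, x = x3, v = matrix(0, n, 3),
                 restraint_k = 0, restraint_ref = NULL),
            class = "mini_md")
}

#' Maxwell-Boltzmann thermal velocities
#'
#' Draws velocities at temperature `T` (each component with variance
#' k_B T / m_i) and removes the center-of-mass drift.
#'
#' @param top an `fftop`
#' @param temperature target temperature (K)
#' @return N x 3 velocity matrix (nm/ps); set the RNG seed beforehand for
#'   reproducibility
#' @export
maxwell_velocities <- function(top, temperature) {
  m <- top$atoms$mass
  n <- length(m)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(.KB * temperature / m)
  sweep(v, 2, colSums(v * m) / sum(m))
}

#' Overwrite velocities of selected atoms with a pulse
#'
#' Either a fixed velocity vector or a radially outward in-plane (xy)
#' pulse about a center; 1 km/s = 1 nm/ps, so speeds in km/s can be passed
#' directly.
#'
#' @param state a `mini_md` state
#' @param selection integer atom indices (nonempty)
#' @param velocity length-3 velocity vector (nm/ps), or `NULL` to use
#'   `radial_speed`
#' @param radial_speed in-plane radial speed (nm/ps) about `center`
#' @param center length-3 reference point for the radial mode (default:
#'   centroid of the selection)
#' @return the modified `mini_md` state
#' @export
apply_velocity_pulse <- function(state, selection, velocity = NULL,
                                 radial_speed = NULL, center = NULL) {
  if (length(selection) == 0) stop("empty selection", call. = FALSE)
  if (is.null(velocity) == is.null(radial_speed))
    stop("give exactly one of 'velocity' or 'radial_speed'", call. = FALSE)
  if (!is.null(velocity)) {
    state$v[selection, ] <- matrix(velocity, length(selection), 3, byrow = TRUE)
  } else {
    if (is.null(center)) center <- colMeans(state$x[selection, , drop = FALSE])
    for (i in selection) {
      d <- state$x[i, ] - center
      d[3] <- 0
      nd <- sqrt(sum(d * d))
      u <- if (nd > 1e-12) d / nd else c(1, 0, 0)
      state$v[i, ] <- radial_speed * u
    }
  }
  state
}

#' Energy minimization of a state
#'
#' FIRE (fast inertial relaxation engine) minimization of the full force
#' field, used to relax built lattices to a force minimum before assigning
#' thermal velocities.
#'
#' @param state a `mini_md` state
#' @param cutoff nonbonded cutoff (nm)
#' @param max_steps iteration cap
#' @param ftol convergence threshold on the largest force component
#'   (kJ/mol/nm)
#' @return the state with minimized coordinates; attributes `epot`, `fmax`,
#'   `steps` report the final energy, residual force and iterations used
#' @export
minimize_energy <- function(state, cutoff = 1.0, max_steps = 5000,
                            ftol = 1.0) {
  res <- .cpp_minimize(state$x, .top_cpp(state$top), cutoff, numeric(0),
                       as.integer(max_steps), ftol, 200L)
  state$x <- res$coords
  attr(state, "epot") <- res$epot
  attr(state, "fmax") <- res$fmax
  attr(state, "steps") <- res$steps
  state
}

#' Velocity-Verlet NVE integration
#'
#' Minimal symplectic integrator over the full force field (bonds, angles,
#' dihedrals, LJ, Coulomb with exclusions and scaled 1-4 pairs). An
#' optional weak harmonic position restraint acts on the dynamics but is
#' never part of any stress term.
#'
#' @param state a `mini_md` state (`top`, `x`, `v`)
#' @param dt time step (ps)
#' @param steps number of steps
#' @param stride snapshot stride (steps between saved frames)
#' @param cutoff nonbonded cutoff (nm)
#' @param skin neighbor-list skin (nm)
#' @param restraint_k harmonic restraint constant (kJ/mol/nm^2; 0 = off)
#' @param restraint_ref reference coordinates for the restraint (default:
#'   starting coordinates)
#' @return list of `mdframe` objects (with velocities); attribute
#'   `energies` holds per-snapshot potential/kinetic energies (kJ/mol)
#' @export
nve_integrate <- function(state, dt, steps, stride = 1L, cutoff = 1.0,
                          skin = 0.2, restraint_k = state$restraint_k,
                          restraint_ref = state$restraint_ref) {
  stopifnot(dt > 0, steps >= 1, stride >= 1)
  if (is.null(restraint_k)) restraint_k <- 0
  ref <- if (is.null(restraint_ref)) state$x else restraint_ref
  res <- .cpp_nve(state$x, state$v, .top_cpp(state$top), dt,
                  as.integer(steps), as.integer(stride), cutoff, skin,
                  restraint_k, ref, numeric(0), 200L)
  nf <- length(res$times)
  frames <- vector("list", nf)
  for (q in seq_len(nf))
    frames[[q]] <- mdframe(res$coords[, , q], time = res$times[q],
                           v = res$velocities[, , q])
  attr(frames, "energies") <- data.frame(time = res$times, epot = res$epot,
                                         ekin = res$ekin,
                                         etot = res$epot + res$ekin)
  frames
}

#' Wavefront propagation speed from a stress trajectory
#'
#' Per frame, the front radius is the largest distance from `origin` among
#' atoms whose front metric exceeds an adaptive threshold (a fraction of
#' that frame's maximum). The metric is |mean principal stress| for the
#' tensile front, or |out-of-plane displacement| relative to the first
#' frame for the transverse wave. The speed is the least-squares slope of
#' radius versus time (nm/ps = km/s).
#'
#' @param frames list of `mdframe` objects
#' @param origin length-3 excitation center (nm)
#' @param mode `"tensile-front"` (needs `stress`) or
#'   `"transverse-displacement"`
#' @param stress an `atom_stress` data.frame aligned with `frames`
#'   (required for the tensile mode; its `total` column is used)
#' @param threshold threshold fraction of the per-frame metric maximum
#'   (default 0.25)
#' @param max_radius fit only frames whose front radius is below this value
#'   (nm); caps the fit before the front reaches a free edge
#' @param min_frames minimum number of usable frames (default 5)
#' @return list: `speed_km_s`, `r_squared`, `n_frames`, `fit` (data.frame
#'   of time/radius pairs used), `intercept_nm`
#' @export
measure_wavefront_speed <- function(frames, origin,
                                    mode = c("tensile-front",
                                             "transverse-displacement"),
                                    stress = NULL, threshold = 0.25,
                                    max_radius = Inf, min_frames = 5) {
  mode <- match.arg(mode)
  if (mode == "tensile-front" && is.null(stress))
    stop("tensile-front mode requires the per-atom 'stress' table", call. = FALSE)
  times <- vapply(frames, function(f) f$time, numeric(1))
  x0 <- frames[[1]]$x
  rad <- rep(NA_real_, length(frames))
  for (q in seq_along(frames)) {
    if (mode == "tensile-front") {
      metric <- abs(stress$total[stress$frame == q])
      if (length(metric) != nrow(frames[[q]]$x))
        stop("stress table does not align with frames", call. = FALSE)
    } else {
      metric <- abs(frames[[q]]$x[, 3] - x0[, 3])
    }
    mx <- max(metric)
    if (!is.finite(mx) || mx <= 0) next
    act <- which(metric > threshold * mx)
    if (length(act) == 0) next
    d <- sweep(frames[[q]]$x[act, , drop = FALSE], 2, origin)
    rad[q] <- sqrt(max(rowSums(d * d)))
  }
  use <- which(is.finite(rad) & rad <= max_radius)
  if (length(use) < min_frames)
    stop(sprintf("no detectable front: only %d of %d frames usable (need >= %d)",
                 length(use), length(frames), min_frames), call. = FALSE)
  fit <- stats::lm(rad[use] ~ times[use])
  tss <- sum((rad[use] - mean(rad[use]))^2)
  rsq <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(speed_km_s = unname(coef(fit)[2]),
       r_squared = rsq,
       n_frames = length(use),
       fit = data.frame(time = times[use], radius = rad[use]),
       intercept_nm = unname(coef(fit)[1]))
}
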