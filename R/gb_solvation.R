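## Onufriev-Bashford-Case (OBC) generalized Born implicit solvation:
## effective Born radii via HCT pairwise descreening integrals with the OBC
## tanh rescaling, the Still-type pairwise polar solvation energy, and its
## decomposition into central pairwise forces via the chain rule through the
## Born radii. Chain-rule terms dG/dR_k * dR_k/dr_kj are attributed to the
## pair (k, j) whose distance enters the descreening integral, so every
## contribution is central and the resulting per-atom stress is symmetric.

#' Generalized-Born model parameters
#'
#' Defaults are the OBC-II coefficients with the standard 0.009 nm radius
#' offset and a water/vacuum dielectric pair.
#'
#' @param dielectric_solvent solvent dielectric constant (default 80)
#' @param dielectric_solute solute interior dielectric (default 1)
#' @param offset intrinsic-radius offset (nm, default 0.009)
#' @param alpha,beta,gamma OBC-II tanh-rescaling coefficients
#'   (1.0, 0.8, 4.85)
#' @param cutoff pair cutoff for descreening and energy sums (nm, default
#'   `Inf`)
#' @return list of class `gb_params`
#' @export
gb_params <- function(dielectric_solvent = 80, dielectric_solute = 1,
                      offset = 0.009, alpha = 1.0, beta = 0.8, gamma = 4.85,
                      cutoff = Inf) {
  if (!(dielectric_solvent > dielectric_solute && dielectric_solute >= 1))
    stop("require dielectric_solvent > dielectric_solute >= 1")
  structure(list(dielectric_solvent = dielectric_solvent,
                 dielectric_solute = dielectric_solute,
                 offset = offset, alpha = alpha, beta = beta, gamma = gamma,
                 cutoff = cutoff), class = "gb_params")
}

# HCT descreening term for atom with offset radius rho descreened by a
# neighbor with scaled radius s at distance r, and its d/dr. The 1/2
# prefactor of the integral is applied by the caller.
.hct_term <- function(r, rho, s) {
  if (rho >= r + s) return(c(0, 0))
  U <- r + s
  engulfed <- rho < s - r
  if (rho > abs(r - s)) {
    L <- rho; dL <- 0
  } else {
    L <- abs(r - s); dL <- sign(r - s)
  }
  iL <- 1 / L; iU <- 1 / U
  val <- iL - iU + 0.25 * r * (iU^2 - iL^2) + (0.5 / r) * log(L / U) +
    (s^2 / (4 * r)) * (iL^2 - iU^2)
  der <- -dL * iL^2 + iU^2 +
    0.25 * (iU^2 - iL^2) + 0.25 * r * (-2 * iU^3 + 2 * dL * iL^3) +
    (-0.5 / r^2) * log(L / U) + (0.5 / r) * (dL * iL - iU) +
    (-s^2 / (4 * r^2)) * (iL^2 - iU^2) +
    (s^2 / (4 * r)) * (-2 * dL * iL^3 + 2 * iU^3)
  if (engulfed) {
    val <- val + 2 * (1 / rho - iL)
    der <- der + 2 * dL * iL^2
  }
  c(val, der)
}

.gb_atom_params <- function(atoms, params) {
  rho <- atoms$gb_radius
  scr <- atoms$gb_screen
  if (any(!is.finite(rho)) || any(!is.finite(scr))) {
    bad <- which(!is.finite(rho) | !is.finite(scr))
    stop("GB parameters missing for atom(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (any(rho <= params$offset))
    stop("all GB intrinsic radii must exceed the offset ", params$offset, " nm",
         call. = FALSE)
  list(rho = rho, rho_t = rho - params$offset, s = scr * (rho - params$offset))
}

#' Compute OBC effective Born radii
#'
#' For each atom the HCT descreening integrals are summed into Psi_i, then
#' R_i^-1 = rho_t_i^-1 - tanh(alpha Psi - beta Psi^2 + gamma Psi^3) / rho_i
#' with rho_t_i = rho_i - offset.
#'
#' @param x N x 3 coordinates (nm)
#' @param atoms data.frame with `gb_radius` (nm) and `gb_screen` columns
#'   (the `atoms` table of an `fftop`)
#' @param params a [gb_params()] object
#' @return list with `born_radius` and `psi` vectors (class
#'   `born_radii`)
#' @export
compute_born_radii <- function(x, atoms, params = gb_params()) {
  x <- as.matrix(x)
  ap <- .gb_atom_params(atoms, params)
  n <- nrow(x)
  if (nrow(atoms) != n) stop("coordinate/atom table length mismatch")
  I <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- x[i, ] - x[j, ]
      r <- sqrt(sum(d * d))
      if (r > params$cutoff) next
      if (r <= 0) .degenerate("gb", "overlapping identical coordinates")
      I[i] <- I[i] + .hct_term(r, ap$rho_t[i], ap$s[j])[1]
    }
  }
  psi <- 0.5 * I * ap$rho_t
  u <- params$alpha * psi - params$beta * psi^2 + params$gamma * psi^3
  inv_r <- 1 / ap$rho_t - tanh(u) / ap$rho
  if (any(inv_r <= 0)) stop("non-positive inverse Born radius encountered")
  structure(list(born_radius = 1 / inv_r, psi = psi), class = "born_radii")
}

# Still pair function and partials
.fgb <- function(r, Ri, Rj) {
  D <- exp(-r^2 / (4 * Ri * Rj))
  f <- sqrt(r^2 + Ri * Rj * D)
  list(f = f, D = D,
       df_dr = r * (1 - D / 4) / f,
       df_dRi = (D / (2 * f)) * (Rj + r^2 / (4 * Ri)),
       df_dRj = (D / (2 * f)) * (Ri + r^2 / (4 * Rj)))
}

#' Generalized-Born polar solvation energy
#'
#' Still-type pairwise expression including Born self terms:
#' G = -f (1/eps_in - 1/eps_solv) (sum over i of q_i^2 / (2 R_i), plus sum
#' over pairs i < j of q_i q_j / f_GB(r_ij, R_i, R_j)), with
#' f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j))).
#'
#' @param x N x 3 coordinates (nm)
#' @param charges atomic charges (e)
#' @param born radii object from [compute_born_radii()] (or a numeric vector
#'   of Born radii)
#' @param params a [gb_params()] object
#' @return solvation energy (kJ/mol)
#' @export
gb_energy <- function(x, charges, born, params = gb_params()) {
  x <- as.matrix(x)
  R <- if (inherits(born, "born_radii")) born$born_radius else as.numeric(born)
  n <- nrow(x)
  if (length(charges) != n || length(R) != n)
    stop("coordinates, charges and Born radii must have matching lengths")
  C <- .COULOMB_K * (1 / params$dielectric_solute - 1 / params$dielectric_solvent)
  e <- sum(charges^2 / (2 * R))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- x[i, ] - x[j, ]
      r <- sqrt(sum(d * d))
      if (r > params$cutoff) next
      e <- e + charges[i] * charges[j] / .fgb(r, R[i], R[j])$f
    }
  }
  -C * e
}

#' Pairwise GB stress forces
#'
#' Decomposes the gradient of the full GB composition (descreening
#' integrals, OBC radii, Still energy) into central pairwise forces: the
#' direct f_GB distance dependence plus every chain-rule path
#' dG/dR_k * dR_k/dr_kj, attributed to the pair (k, j). Per-atom sums of the
#' returned records reproduce -grad G.
#'
#' @param x N x 3 coordinates (nm)
#' @param atoms data.frame with `charge`, `gb_radius`, `gb_screen` columns
#' @param params a [gb_params()] object
#' @return pair-force data.frame with term `"gb"` (force on atom `i` of each
#'   pair, kJ/mol/nm)
#' @export
gb_pair_forces <- function(x, atoms, params = gb_params()) {
  x <- as.matrix(x)
  n <- nrow(x)
  q <- atoms$charge
  empty_pf <- data.frame(i = integer(0), j = integer(0), fx = numeric(0),
                         fy = numeric(0), fz = numeric(0), term = character(0),
                         stringsAsFactors = FALSE)
  if (all(q == 0)) return(empty_pf)
  ap <- .gb_atom_params(atoms, params)
  born <- compute_born_radii(x, atoms, params)
  R <- born$born_radius
  psi <- born$psi
  C <- .COULOMB_K * (1 / params$dielectric_solute - 1 / params$dielectric_solvent)

  # dG/dR_k: self terms + pair terms
  dG_dR <- C * q^2 / (2 * R^2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- x[i, ] - x[j, ]
      r <- sqrt(sum(d * d))
      if (r > params$cutoff) next
      fg <- .fgb(r, R[i], R[j])
      cc <- C * q[i] * q[j] / fg$f^2
      dG_dR[i] <- dG_dR[i] + cc * fg$df_dRi
      dG_dR[j] <- dG_dR[j] + cc * fg$df_dRj
    }
  }
  # dR_k/dPsi_k
  u <- params$alpha * psi - params$beta * psi^2 + params$gamma * psi^3
  du <- params$alpha - 2 * params$beta * psi + 3 * params$gamma * psi^2
  dR_dPsi <- R^2 * (1 / cosh(u))^2 * du / ap$rho

  rows <- vector("list", n * (n - 1) / 2)
  nr <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- x[i, ] - x[j, ]
      r <- sqrt(sum(d * d))
      if (r > params$cutoff) next
      g <- 0
      # direct f_GB dependence of the (i, j) pair energy
      fg <- .fgb(r, R[i], R[j])
      g <- g + C * q[i] * q[j] / fg$f^2 * fg$df_dr
      # chain through Psi_i (descreening of i by j) and Psi_j (by i)
      hi <- .hct_term(r, ap$rho_t[i], ap$s[j])[2]
      hj <- .hct_term(r, ap$rho_t[j], ap$s[i])[2]
      g <- g + dG_dR[i] * dR_dPsi[i] * 0.5 * ap$rho_t[i] * hi
      g <- g + dG_dR[j] * dR_dPsi[j] * 0.5 * ap$rho_t[j] * hj
      if (g != 0) {
        nr <- nr + 1L
        rows[[nr]] <- .pf(i, j, -g * d / r, "gb")
      }
    }
  }
  if (nr == 0L) return(empty_pf)
  do.call(rbind, rows[seq_len(nr)])
}
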