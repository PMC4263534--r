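## Per-term potential energies, evaluated directly from the topology.
## These are the quantities the finite-difference force oracle
## differentiates; they deliberately share no code with the pairwise force
## decomposition they are used to validate.

#' Per-term potential energy of a configuration
#'
#' @param top an `fftop` topology
#' @param x N x 3 coordinates (nm)
#' @param box optional orthorhombic box edges (nm; minimum image for
#'   nonbonded pairs)
#' @param cutoff nonbonded cutoff (nm); bonded terms are always evaluated
#' @param gb optional [gb_params()]; GB energy computed only when the
#'   topology carries complete GB parameters and any charge is nonzero
#' @param terms subset of term names to evaluate
#' @return named numeric vector of term energies (kJ/mol), one element per
#'   requested term
#' @export
term_energies <- function(top, x, box = NULL, cutoff = Inf,
                          gb = gb_params(),
                          terms = c("bond", "angle", "dihedral",
                                    "coulomb", "vdw", "gb")) {
  x <- as.matrix(x)
  n <- n_atoms(top)
  stopifnot(nrow(x) == n)
  mi <- function(d) if (is.null(box)) d else d - box * round(d / box)
  out <- setNames(numeric(length(terms)), terms)

  if ("bond" %in% terms && nrow(top$bonds) > 0) {
    b <- top$bonds
    d <- mi(x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE])
    r <- sqrt(rowSums(d * d))
    out["bond"] <- sum(0.5 * b$kb * (r - b$b0)^2)
  }
  if ("angle" %in% terms && nrow(top$angles) > 0) {
    a <- top$angles
    u <- x[a$i, , drop = FALSE] - x[a$j, , drop = FALSE]
    v <- x[a$k, , drop = FALSE] - x[a$j, , drop = FALSE]
    ct <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
    th <- acos(pmin(1, pmax(-1, ct)))
    out["angle"] <- sum(0.5 * a$ktheta * (th - a$theta0)^2)
  }
  if ("dihedral" %in% terms && nrow(top$dihedrals) > 0) {
    dh <- top$dihedrals
    phi <- vapply(seq_len(nrow(dh)), function(q) {
      .dihedral_geometry(x[dh$i[q], ], x[dh$j[q], ],
                         x[dh$k[q], ], x[dh$l[q], ])$phi
    }, numeric(1))
    out["dihedral"] <- sum(dh$kphi * (1 + cos(dh$mult * phi - dh$phase)))
  }

  need_nb <- any(c("coulomb", "vdw") %in% terms)
  if (need_nb && n > 1) {
    excl <- paste(pmin(top$exclusions$i, top$exclusions$j),
                  pmax(top$exclusions$i, top$exclusions$j))
    p14 <- top$pairs14
    key14 <- paste(pmin(p14$i, p14$j), pmax(p14$i, p14$j))
    ec <- 0; ev <- 0
    a <- top$atoms
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        key <- paste(i, j)
        if (key %in% excl) next
        qs <- 1; ls <- 1
        w <- match(key, key14)
        if (!is.na(w)) { qs <- p14$qscale[w]; ls <- p14$ljscale[w] }
        d <- mi(x[i, ] - x[j, ])
        r <- sqrt(sum(d * d))
        if (r > cutoff) next
        ec <- ec + qs * .COULOMB_K * a$charge[i] * a$charge[j] / r
        sig <- 0.5 * (a$sigma[i] + a$sigma[j])
        eps <- sqrt(a$epsilon[i] * a$epsilon[j])
        sr6 <- (sig / r)^6
        ev <- ev + ls * 4 * eps * (sr6 * sr6 - sr6)
      }
    }
    if ("coulomb" %in% terms) out["coulomb"] <- ec
    if ("vdw" %in% terms) out["vdw"] <- ev
  }

  if ("gb" %in% terms && all(is.finite(top$atoms$gb_radius)) &&
      any(top$atoms$charge != 0)) {
    born <- compute_born_radii(x, top$atoms, gb)
    out["gb"] <- gb_energy(x, top$atoms$charge, born, gb)
  }
  out
}
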