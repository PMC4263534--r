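## Per-atom mean principal virial stress assembly.
##
## For each atom i the per-term mean principal stress is
##   sigma_i = 1/(6 V_i) * sum_over_pairs (r_j - r_i) . f_ij
## (trace/3 of the pair virial, computed as dot products; the 3x3 tensor is
## never assembled). Sign convention: a stretched bond gives positive
## (tensile) stress and negative hydrostatic pressure; an ideal gas gives
## positive hydrostatic pressure. Output unit is kbar via
## 1 kJ/mol/nm^3 = 16.6054 bar.

#' Stress-calculation options
#'
#' @param cutoff nonbonded cutoff (nm, default 1.0). Bonded-term pairs are
#'   always included regardless of the cutoff.
#' @param include_kinetic include the kinetic (velocity) stress term;
#'   requires velocities in the frames
#' @param carbon_volume per-atom characteristic volume used when no box is
#'   present (nm^3, default 0.0206 = a 1.7 Angstrom van der Waals sphere)
#' @param selection optional integer vector of atom indices to report
#'   (stress is still computed from all interactions)
#' @param gb include the generalized-Born solvent term when the topology
#'   carries complete GB parameters and nonzero charges
#' @param gb_params a [gb_params()] object; default uses `cutoff` for the GB
#'   sums
#' @param remove_com_velocity subtract the selection's center-of-mass
#'   velocity before the kinetic term (local-frame reference; off by
#'   default)
#' @param brute_limit below this atom count pair enumeration is brute-force
#'   O(N^2); above it a cell list is used (equivalent by construction)
#' @return list of class `stress_options`
#' @export
stress_options <- function(cutoff = 1.0, include_kinetic = FALSE,
                           carbon_volume = 0.0206, selection = NULL,
                           gb = TRUE, gb_params = NULL,
                           remove_com_velocity = FALSE, brute_limit = 200) {
  stopifnot(cutoff > 0, carbon_volume > 0)
  if (is.null(gb_params)) gb_params <- gb_params(cutoff = cutoff)
  structure(list(cutoff = cutoff, include_kinetic = include_kinetic,
                 carbon_volume = carbon_volume, selection = selection,
                 gb = gb, gb_params = gb_params,
                 remove_com_velocity = remove_com_velocity,
                 brute_limit = as.integer(brute_limit)),
            class = "stress_options")
}

# topology in the flat-array layout the compiled kernels consume
.top_cpp <- function(top) {
  n <- n_atoms(top)
  imat <- function(df, cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "integer"
    if (nrow(m) == 0) m <- matrix(integer(0), 0, length(cols))
    m
  }
  key <- function(i, j) (pmin(i, j) - 1) * n + (pmax(i, j) - 1)
  sk <- numeric(0)
  if (nrow(top$exclusions) > 0)
    sk <- c(sk, key(top$exclusions$i, top$exclusions$j))
  if (nrow(top$pairs14) > 0)
    sk <- c(sk, key(top$pairs14$i, top$pairs14$j))
  list(mass = top$atoms$mass, charge = top$atoms$charge,
       sigma = top$atoms$sigma, epsilon = top$atoms$epsilon,
       bonds = imat(top$bonds, c("i", "j")),
       kb = as.numeric(top$bonds$kb), b0 = as.numeric(top$bonds$b0),
       angles = imat(top$angles, c("i", "j", "k")),
       ktheta = as.numeric(top$angles$ktheta),
       theta0 = as.numeric(top$angles$theta0),
       dihedrals = imat(top$dihedrals, c("i", "j", "k", "l")),
       kphi = as.numeric(top$dihedrals$kphi),
       mult = as.integer(top$dihedrals$mult),
       phase = as.numeric(top$dihedrals$phase),
       pairs14 = imat(top$pairs14, c("i", "j")),
       qscale = as.numeric(top$pairs14$qscale),
       ljscale = as.numeric(top$pairs14$ljscale),
       skip_keys = as.numeric(sort(sk)))
}

.check_box_cutoff <- function(box, cutoff) {
  if (!is.null(box) && cutoff > min(box) / 2)
    stop(sprintf("cutoff %g nm exceeds half the shortest box edge (%g nm): minimum-image ambiguity",
                 cutoff, min(box)), call. = FALSE)
}

.check_phases <- function(top) {
  ph <- top$dihedrals$phase
  if (length(ph) > 0 && any(pmin(abs(ph), abs(ph - pi), abs(ph + pi)) > 1e-9))
    stop("unsupported dihedral phase: pairwise stress decomposition requires phase 0 or pi",
         call. = FALSE)
}

#' Per-atom characteristic volumes
#'
#' With a box, every atom gets V_box / N (so the volumes sum to the box
#' volume); without one, every atom gets the carbon-atom volume. The policy
#' is decided from the first frame and held constant over a trajectory.
#'
#' @param top an `fftop` topology
#' @param frame an `mdframe` (its box decides the policy)
#' @param options a [stress_options()] object
#' @return list with `v` (per-atom volumes, nm^3) and `policy`
#'   (`"box_uniform"` or `"carbon_default"`)
#' @export
characteristic_volumes <- function(top, frame, options = stress_options()) {
  n <- n_atoms(top)
  if (!is.null(frame$box)) {
    vb <- prod(frame$box)
    if (vb <= 0) stop("zero-volume box", call. = FALSE)
    list(v = rep(vb / n, n), policy = "box_uniform")
  } else {
    list(v = rep(options$carbon_volume, n), policy = "carbon_default")
  }
}

#' Enumerate interacting pairs for one frame
#'
#' Bonded-term pairs come from the topology regardless of the cutoff;
#' nonbonded pairs are all pairs within the cutoff minus exclusions and 1-4
#' pairs, the latter returned separately with their scale factors.
#' Minimum-image displacements are used when the frame has a box.
#'
#' @param frame an `mdframe`
#' @param top an `fftop`
#' @param options a [stress_options()]
#' @return list with integer pair matrices `bond`, `angle` (3 pairs per
#'   instance), `dihedral` (6 pairs per instance), `nonbonded`, and the
#'   `pairs14` data.frame
#' @export
enumerate_pairs <- function(frame, top, options = stress_options()) {
  .check_box_cutoff(frame$box, options$cutoff)
  box <- if (is.null(frame$box)) numeric(0) else frame$box
  allp <- .cpp_nb_pairs(frame$x, options$cutoff, box, options$brute_limit)
  n <- n_atoms(top)
  key <- function(i, j) (pmin(i, j) - 1) * n + (pmax(i, j) - 1)
  skip <- c(if (nrow(top$exclusions) > 0) key(top$exclusions$i, top$exclusions$j),
            if (nrow(top$pairs14) > 0) key(top$pairs14$i, top$pairs14$j))
  if (nrow(allp) > 0 && length(skip) > 0)
    allp <- allp[!(key(allp[, 1], allp[, 2]) %in% skip), , drop = FALSE]
  ang <- top$angles
  dih <- top$dihedrals
  list(
    bond = as.matrix(top$bonds[, c("i", "j"), drop = FALSE]),
    angle = if (nrow(ang) > 0)
      rbind(cbind(ang$i, ang$j), cbind(ang$k, ang$j), cbind(ang$i, ang$k))
      else matrix(numeric(0), 0, 2),
    dihedral = if (nrow(dih) > 0)
      rbind(cbind(dih$i, dih$j), cbind(dih$i, dih$k), cbind(dih$i, dih$l),
            cbind(dih$j, dih$k), cbind(dih$j, dih$l), cbind(dih$k, dih$l))
      else matrix(numeric(0), 0, 2),
    nonbonded = allp,
    pairs14 = top$pairs14)
}

#' Per-atom kinetic stress of one frame
#'
#' Kinetic (velocity) contribution to the mean principal stress:
#' -m_i |v_i - vbar|^2 / (3 V_i), always compressive. `vbar` is zero, or the
#' selection's center-of-mass velocity when `remove_com` is set.
#'
#' @param frame an `mdframe` carrying velocities
#' @param top an `fftop`
#' @param volumes result of [characteristic_volumes()]
#' @param remove_com subtract the center-of-mass velocity first
#' @return numeric vector of per-atom kinetic stress (kbar)
#' @export
kinetic_stress <- function(frame, top, volumes, remove_com = FALSE) {
  if (is.null(frame$v))
    stop("kinetic stress requested but the frame carries no velocities",
         call. = FALSE)
  v <- frame$v
  m <- top$atoms$mass
  if (remove_com) {
    vcom <- colSums(v * m) / sum(m)
    v <- sweep(v, 2, vcom)
  }
  (-m * rowSums(v * v) / (3 * volumes$v)) * .PRESFAC_KBAR
}

.gb_applicable <- function(top, options) {
  options$gb && all(is.finite(top$atoms$gb_radius)) &&
    all(is.finite(top$atoms$gb_screen)) && any(top$atoms$charge != 0)
}

#' Per-atom mean principal stress of one frame
#'
#' Assembles the per-term virial sums (bond, angle, dihedral, Coulomb, van
#' der Waals, and, when applicable, generalized-Born and kinetic), divides
#' by 6 V_i and converts to kbar.
#'
#' @param frame an `mdframe`
#' @param top an `fftop`
#' @param options a [stress_options()]
#' @param volumes optional precomputed [characteristic_volumes()] (computed
#'   from this frame if omitted)
#' @return data.frame with one row per selected atom: `atom`, `time`,
#'   `resid`, the per-term stresses, `total` and `hydrostatic_pressure`
#'   (all kbar)
#' @export
frame_atom_stress <- function(frame, top, options = stress_options(),
                              volumes = NULL) {
  .check_box_cutoff(frame$box, options$cutoff)
  .check_phases(top)
  if (is.null(volumes)) volumes <- characteristic_volumes(top, frame, options)
  n <- n_atoms(top)
  stopifnot(nrow(frame$x) == n)
  box <- if (is.null(frame$box)) numeric(0) else frame$box
  res <- .cpp_frame_virials(frame$x, .top_cpp(top), options$cutoff, box,
                            options$brute_limit)
  vir <- res$virials # n x 5: bond, angle, dihedral, coulomb, vdw (kJ/mol)
  gb_col <- numeric(n)
  if (.gb_applicable(top, options)) {
    pf <- gb_pair_forces(frame$x, top$atoms, options$gb_params)
    if (nrow(pf) > 0) {
      d <- frame$x[pf$j, , drop = FALSE] - frame$x[pf$i, , drop = FALSE]
      val <- rowSums(d * as.matrix(pf[, c("fx", "fy", "fz")]))
      for (q in seq_len(nrow(pf))) {
        gb_col[pf$i[q]] <- gb_col[pf$i[q]] + val[q]
        gb_col[pf$j[q]] <- gb_col[pf$j[q]] + val[q]
      }
    }
  }
  scale <- .PRESFAC_KBAR / (6 * volumes$v)
  out <- data.frame(atom = seq_len(n), time = frame$time,
                    resid = top$atoms$resid,
                    bond = vir[, 1] * scale, angle = vir[, 2] * scale,
                    dihedral = vir[, 3] * scale, coulomb = vir[, 4] * scale,
                    vdw = vir[, 5] * scale, gb = gb_col * scale,
                    kinetic = 0)
  if (options$include_kinetic)
    out$kinetic <- kinetic_stress(frame, top, volumes,
                                  remove_com = options$remove_com_velocity)
  out$total <- out$bond + out$angle + out$dihedral + out$coulomb +
    out$vdw + out$gb + out$kinetic
  out$hydrostatic_pressure <- -out$total
  if (!is.null(options$selection))
    out <- out[out$atom %in% options$selection, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-atom stress over a trajectory
#'
#' The characteristic-volume policy is decided from the first frame and
#' held constant.
#'
#' @param top an `fftop`
#' @param frames list of `mdframe` objects
#' @param options a [stress_options()]
#' @return data.frame of class `atom_stress`: rows are (frame, atom), with a
#'   `frame` index column plus the columns of [frame_atom_stress()]
#' @export
atom_stress <- function(top, frames, options = stress_options()) {
  if (inherits(frames, "mdframe")) frames <- list(frames)
  if (length(frames) == 0) stop("no frames supplied")
  volumes <- characteristic_volumes(top, frames[[1]], options)
  res <- vector("list", length(frames))
  for (q in seq_along(frames)) {
    df <- tryCatch(
      frame_atom_stress(frames[[q]], top, options, volumes),
      error = function(e) stop(sprintf("frame %d (t=%g ps): %s", q,
                                       frames[[q]]$time, conditionMessage(e)),
                               call. = FALSE))
    df <- cbind(frame = q, df)
    res[[q]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("atom_stress", "data.frame")
  out
}
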