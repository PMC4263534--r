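## Data model and file I/O: portable topology / trajectory formats and
## GROMACS-style index (.ndx) files. All atom indices are 1-based, both
## in memory and in the portable file formats.

#' Construct a force-field topology
#'
#' The central container consumed by all stress calculations. All numeric
#' fields use the internal unit system: nm, ps, amu, kJ/mol, elementary
#' charges, radians.
#'
#' @param atoms data.frame with columns `name`, `resid` (integer residue id),
#'   `resname`, `mass` (amu, > 0), `charge` (e), `sigma` (nm, >= 0),
#'   `epsilon` (kJ/mol, >= 0) and optionally `gb_radius` (nm) and
#'   `gb_screen` (dimensionless) for generalized-Born solvation.
#' @param bonds data.frame `i, j, kb, b0`: harmonic bonds
#'   V = 1/2 kb (b - b0)^2 with kb in kJ/mol/nm^2, b0 in nm.
#' @param angles data.frame `i, j, k, ktheta, theta0` (j is the vertex):
#'   V = 1/2 ktheta (theta - theta0)^2, ktheta in kJ/mol/rad^2, theta0 rad.
#' @param dihedrals data.frame `i, j, k, l, kphi, mult, phase`: periodic
#'   torsions V = kphi (1 + cos(mult * phi - phase)); only phase 0 or pi is
#'   supported by the pairwise stress decomposition.
#' @param pairs14 data.frame `i, j, qscale, ljscale`: 1-4 pairs with their
#'   Coulomb and Lennard-Jones scale factors.
#' @param exclusions data.frame `i, j`: pairs fully excluded from nonbonded
#'   interactions (must be disjoint from `pairs14`).
#' @return An object of class `fftop`.
#' @export
fftop <- function(atoms,
                  bonds = NULL, angles = NULL, dihedrals = NULL,
                  pairs14 = NULL, exclusions = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("name", "resid", "resname", "mass", "charge", "sigma", "epsilon")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$gb_radius)) atoms$gb_radius <- NA_real_
  if (is.null(atoms$gb_screen)) atoms$gb_screen <- NA_real_
  n <- nrow(atoms)
  if (n < 1) stop("topology must contain at least one atom")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atom masses must be positive")
  if (any(atoms$sigma < 0) || any(atoms$epsilon < 0))
    stop("Lennard-Jones sigma and epsilon must be non-negative")

  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  bonds <- .coerce_term(bonds, c("i", "j", "kb", "b0"), empty)
  angles <- .coerce_term(angles, c("i", "j", "k", "ktheta", "theta0"), empty)
  dihedrals <- .coerce_term(dihedrals,
                            c("i", "j", "k", "l", "kphi", "mult", "phase"),
                            empty)
  pairs14 <- .coerce_term(pairs14, c("i", "j", "qscale", "ljscale"), empty)
  exclusions <- .coerce_term(exclusions, c("i", "j"), empty)

  chk_idx <- function(df, cols, what) {
    for (cl in cols) {
      v <- df[[cl]]
      if (length(v) && (any(v != round(v)) || any(v < 1) || any(v > n)))
        stop(sprintf("%s: atom index out of range 1..%d", what, n))
    }
    if (nrow(df) > 0) {
      idx <- as.matrix(df[, cols, drop = FALSE])
      if (any(apply(idx, 1L, anyDuplicated) > 0))
        stop(what, ": atom indices within a term must be distinct")
    }
  }
  chk_idx(bonds, c("i", "j"), "bonds")
  chk_idx(angles, c("i", "j", "k"), "angles")
  chk_idx(dihedrals, c("i", "j", "k", "l"), "dihedrals")
  chk_idx(pairs14, c("i", "j"), "pairs14")
  chk_idx(exclusions, c("i", "j"), "exclusions")
  if (nrow(dihedrals) > 0 && any(dihedrals$mult < 1))
    stop("dihedral multiplicity must be >= 1")

  key <- function(df) {
    if (nrow(df) == 0) return(character(0))
    paste(pmin(df$i, df$j), pmax(df$i, df$j))
  }
  if (length(intersect(key(exclusions), key(pairs14))) > 0)
    stop("exclusions and pairs14 must be disjoint")

  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, pairs14 = pairs14,
                 exclusions = exclusions),
            class = "fftop")
}

.coerce_term <- function(df, cols, empty) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0)) return(empty(cols))
  df <- as.data.frame(df)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop("term table missing column(s): ", paste(miss, collapse = ", "))
  df[, cols, drop = FALSE]
}

#' Number of atoms in a topology
#' @param top an `fftop` object
#' @return integer atom count
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Residue map of a topology
#' @param top an `fftop` object
#' @return named list: residue id -> integer vector of atom indices
#' @export
residue_map <- function(top) {
  split(seq_len(n_atoms(top)), top$atoms$resid)
}

#' @export
print.fftop <- function(x, ...) {
  cat(sprintf("Force-field topology: %d atoms, %d residues\n",
              n_atoms(x), length(unique(x$atoms$resid))))
  cat(sprintf("  bonds: %d  angles: %d  dihedrals: %d  pairs14: %d  exclusions: %d\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$pairs14), nrow(x$exclusions)))
  cat(sprintf("  GB parameters: %s\n",
              if (all(is.finite(x$atoms$gb_radius))) "complete"
              else if (any(is.finite(x$atoms$gb_radius))) "partial" else "absent"))
  invisible(x)
}

#' Construct a trajectory frame
#'
#' @param x N x 3 coordinate matrix (nm)
#' @param time frame time (ps)
#' @param v optional N x 3 velocity matrix (nm/ps)
#' @param box optional length-3 vector of orthorhombic box edges (nm)
#' @return object of class `mdframe`
#' @export
mdframe <- function(x, time = 0, v = NULL, box = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must be an N x 3 matrix")
  if (!is.null(v)) {
    v <- as.matrix(v)
    if (!all(dim(v) == dim(x))) stop("velocity array must match coordinates")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3) stop("only orthorhombic boxes (3 edge lengths) are supported")
    if (any(box <= 0)) stop("box edge lengths must be positive")
  }
  structure(list(time = as.numeric(time), x = x, v = v, box = box),
            class = "mdframe")
}

## ---------------------------------------------------------------------------
## Portable topology format: sectioned whitespace text, '#' comments.
## Sections: [atoms] [bonds] [angles] [dihedrals] [pairs14] [exclusions] [gb]

#' Write a topology in the portable sectioned text format
#'
#' Columns are whitespace-separated; `#` starts a comment. Units as stored
#' internally (nm, kJ/mol, radians); indices 1-based.
#'
#' @param top an `fftop` object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_topology <- function(top, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  fmt <- function(x) sprintf("%.17g", x)
  w("# portable force-field topology (atomstress)")
  w("# units: nm, kJ/mol, amu, elementary charge, rad; 1-based indices")
  w("[atoms]")
  w("# index name resname resid mass charge sigma epsilon")
  a <- top$atoms
  for (ii in seq_len(nrow(a)))
    w("%d %s %s %d %s %s %s %s", ii, a$name[ii], a$resname[ii],
      as.integer(a$resid[ii]), fmt(a$mass[ii]), fmt(a$charge[ii]),
      fmt(a$sigma[ii]), fmt(a$epsilon[ii]))
  sec <- function(name, df, fmts) {
    w("[%s]", name)
    for (ii in seq_len(nrow(df)))
      w("%s", paste(vapply(seq_along(df), function(cl) {
        v <- df[[cl]][ii]
        if (fmts[cl] == "d") sprintf("%d", as.integer(v)) else fmt(v)
      }, character(1)), collapse = " "))
  }
  sec("bonds", top$bonds, c("d", "d", "g", "g"))
  sec("angles", top$angles, c("d", "d", "d", "g", "g"))
  sec("dihedrals", top$dihedrals, c("d", "d", "d", "d", "g", "d", "g"))
  sec("pairs14", top$pairs14, c("d", "d", "g", "g"))
  sec("exclusions", top$exclusions, c("d", "d"))
  if (any(is.finite(a$gb_radius))) {
    w("[gb]")
    w("# index radius screen")
    for (ii in seq_len(nrow(a)))
      if (is.finite(a$gb_radius[ii]))
        w("%d %s %s", ii, fmt(a$gb_radius[ii]), fmt(a$gb_screen[ii]))
  }
  invisible(path)
}

.parse_err <- function(path, lineno, msg) {
  stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
}

#' Read a portable topology file
#'
#' @param path path to a file in the sectioned text format written by
#'   [write_topology()]
#' @return an `fftop` object
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  section <- NA_character_
  rows <- list(atoms = list(), bonds = list(), angles = list(),
               dihedrals = list(), pairs14 = list(), exclusions = list(),
               gb = list())
  known <- names(rows)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s)) next
    if (grepl("^\\[", s)) {
      nm <- trimws(sub("^\\[\\s*([^]]*)\\s*\\].*$", "\\1", s))
      if (!nm %in% known)
        .parse_err(path, ln, paste0("unknown section [", nm, "]"))
      section <- nm
      next
    }
    if (is.na(section)) .parse_err(path, ln, "data before any section header")
    rows[[section]][[length(rows[[section]]) + 1L]] <- list(ln = ln, tok = strsplit(s, "\\s+")[[1]])
  }
  if (length(rows$atoms) == 0)
    stop(sprintf("%s: missing or empty [atoms] section", path), call. = FALSE)

  num <- function(tok, k, ln) {
    v <- suppressWarnings(as.numeric(tok[k]))
    if (any(is.na(v))) .parse_err(path, ln, paste0("non-numeric field: ", tok[k][which(is.na(v))[1]]))
    v
  }
  natm <- length(rows$atoms)
  atoms <- data.frame(name = character(natm), resname = character(natm),
                      resid = integer(natm), mass = numeric(natm),
                      charge = numeric(natm), sigma = numeric(natm),
                      epsilon = numeric(natm), gb_radius = NA_real_,
                      gb_screen = NA_real_, stringsAsFactors = FALSE)
  for (r in rows$atoms) {
    if (length(r$tok) < 8) .parse_err(path, r$ln, "expected 8 columns in [atoms]")
    idx <- num(r$tok, 1, r$ln)
    if (idx != round(idx) || idx < 1 || idx > natm)
      .parse_err(path, r$ln, sprintf("atom index %s outside 1..%d", r$tok[1], natm))
    atoms$name[idx] <- r$tok[2]
    atoms$resname[idx] <- r$tok[3]
    atoms$resid[idx] <- as.integer(num(r$tok, 4, r$ln))
    atoms[idx, c("mass", "charge", "sigma", "epsilon")] <- num(r$tok, 5:8, r$ln)
  }

  grab <- function(sec, ncol_exp, colnames) {
    rs <- rows[[sec]]
    if (length(rs) == 0) {
      return(as.data.frame(setNames(rep(list(numeric(0)), length(colnames)), colnames)))
    }
    m <- matrix(NA_real_, length(rs), ncol_exp)
    for (q in seq_along(rs)) {
      r <- rs[[q]]
      if (length(r$tok) != ncol_exp)
        .parse_err(path, r$ln, sprintf("expected %d columns in [%s]", ncol_exp, sec))
      m[q, ] <- num(r$tok, seq_len(ncol_exp), r$ln)
      nidx <- sum(colnames %in% c("i", "j", "k", "l"))
      bad <- which(m[q, seq_len(nidx)] < 1 | m[q, seq_len(nidx)] > natm |
                     m[q, seq_len(nidx)] != round(m[q, seq_len(nidx)]))
      if (length(bad) > 0)
        .parse_err(path, r$ln, sprintf("atom index %g outside 1..%d", m[q, bad[1]], natm))
    }
    df <- as.data.frame(m)
    names(df) <- colnames
    df
  }
  bonds <- grab("bonds", 4, c("i", "j", "kb", "b0"))
  angles <- grab("angles", 5, c("i", "j", "k", "ktheta", "theta0"))
  dihedrals <- grab("dihedrals", 7, c("i", "j", "k", "l", "kphi", "mult", "phase"))
  pairs14 <- grab("pairs14", 4, c("i", "j", "qscale", "ljscale"))
  exclusions <- grab("exclusions", 2, c("i", "j"))
  for (r in rows$gb) {
    if (length(r$tok) != 3) .parse_err(path, r$ln, "expected 3 columns in [gb]")
    v <- num(r$tok, 1:3, r$ln)
    if (v[1] != round(v[1]) || v[1] < 1 || v[1] > natm)
      .parse_err(path, r$ln, sprintf("atom index %g outside 1..%d", v[1], natm))
    atoms$gb_radius[v[1]] <- v[2]
    atoms$gb_screen[v[1]] <- v[3]
  }
  fftop(atoms, bonds, angles, dihedrals, pairs14, exclusions)
}

## ---------------------------------------------------------------------------
## Portable trajectory format: per-frame blocks
##   t=<ps>
##   box Lx Ly Lz          (optional)
##   x y z [vx vy vz]      (one line per atom)

#' Write frames in the portable text trajectory format
#'
#' @param frames a list of `mdframe` objects (or a single frame)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(frames, path) {
  if (inherits(frames, "mdframe")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("t=%.17g", fr$time), con)
    if (!is.null(fr$box))
      writeLines(paste("box", paste(sprintf("%.17g", fr$box), collapse = " ")), con)
    m <- if (is.null(fr$v)) fr$x else cbind(fr$x, fr$v)
    writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a portable text trajectory
#'
#' Frames are returned in file order. Velocities are populated only when the
#' file carries 6 columns per atom. A truncated final frame is dropped with
#' a warning.
#'
#' @param path trajectory file path
#' @param top the matching `fftop` topology (atom count check)
#' @return list of `mdframe` objects
#' @export
read_trajectory <- function(path, top) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  n <- n_atoms(top)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  starts <- grep("^t=", lines)
  if (length(starts) == 0) stop(path, ": no frames found (no 't=' lines)")
  ends <- c(starts[-1] - 1L, length(lines))
  frames <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (q in seq_along(starts)) {
    tm <- as.numeric(sub("^t=", "", lines[starts[q]]))
    body <- lines[seq(starts[q] + 1L, length.out = ends[q] - starts[q])]
    box <- NULL
    if (length(body) > 0 && grepl("^box\\s", body[1])) {
      box <- as.numeric(strsplit(body[1], "\\s+")[[1]][-1])
      body <- body[-1]
    }
    if (length(body) < n) {
      warning(sprintf("%s: frame at t=%g ps truncated (%d of %d atom lines); frame dropped",
                      path, tm, length(body), n))
      next
    }
    if (length(body) > n)
      stop(sprintf("%s: frame at t=%g ps has %d atom lines but topology has %d atoms",
                   path, tm, length(body), n))
    m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    if (anyNA(m)) stop(sprintf("%s: non-numeric coordinate in frame at t=%g ps", path, tm))
    if (!ncol(m) %in% c(3L, 6L))
      stop(sprintf("%s: frame at t=%g ps has %d columns; expected 3 or 6", path, tm, ncol(m)))
    v <- if (ncol(m) == 6L) m[, 4:6, drop = FALSE] else NULL
    frames[[q]] <- mdframe(m[, 1:3, drop = FALSE], time = tm, v = v, box = box)
    keep[q] <- TRUE
  }
  frames[keep]
}

## ---------------------------------------------------------------------------

#' Read a GROMACS-style index (.ndx) file
#'
#' Bracketed group names followed by whitespace-separated 1-based atom
#' indices. Indices are deduplicated and sorted; groups are returned in file
#' order.
#'
#' @param path .ndx file path
#' @param n_atoms optional atom count for range validation
#' @return named list of integer vectors (class `ndx`)
#' @export
read_index <- function(path, n_atoms = NULL) {
  if (!file.exists(path)) stop("index file not found: ", path)
  lines <- sub(";.*$", "", readLines(path, warn = FALSE))
  groups <- list()
  current <- NULL
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s)) next
    if (grepl("^\\[", s)) {
      current <- trimws(sub("^\\[\\s*([^]]*)\\s*\\].*$", "\\1", s))
      if (!nzchar(current)) .parse_err(path, ln, "empty group name")
      if (is.null(groups[[current]])) groups[[current]] <- integer(0)
      next
    }
    if (is.null(current)) .parse_err(path, ln, "indices before any group header")
    v <- suppressWarnings(as.integer(strsplit(s, "\\s+")[[1]]))
    if (anyNA(v)) .parse_err(path, ln, "non-integer index")
    if (any(v <= 0)) .parse_err(path, ln, "atom indices must be >= 1")
    if (!is.null(n_atoms) && any(v > n_atoms))
      .parse_err(path, ln, sprintf("atom index exceeds atom count %d", n_atoms))
    groups[[current]] <- c(groups[[current]], v)
  }
  if (length(groups) == 0) stop(path, ": no groups found")
  groups <- lapply(groups, function(g) sort(unique(g)))
  structure(groups, class = "ndx")
}

#' Write index groups in the GROMACS .ndx dialect
#' @param groups named list of integer vectors (1-based)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_index <- function(groups, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(groups)) {
    writeLines(sprintf("[ %s ]", nm), con)
    idx <- as.integer(groups[[nm]])
    for (start in seq(1, length(idx), by = 15))
      writeLines(paste(idx[seq(start, min(start + 14, length(idx)))], collapse = " "), con)
  }
  invisible(path)
}

#' Consistency diagnostics for a topology / trajectory pair
#'
#' Report-only: collects atom-count checks, presence of velocities and box,
#' bonded-term counts, and GB-parameter completeness. Never throws.
#'
#' @param top an `fftop` topology
#' @param frames list of `mdframe` objects
#' @return list with elements `counts`, `notes`, `problems` (class
#'   `system_report`)
#' @export
validate_system <- function(top, frames) {
  if (inherits(frames, "mdframe")) frames <- list(frames)
  n <- n_atoms(top)
  problems <- character(0)
  notes <- character(0)
  has_v <- length(frames) > 0 && all(vapply(frames, function(f) !is.null(f$v), logical(1)))
  has_box <- length(frames) > 0 && all(vapply(frames, function(f) !is.null(f$box), logical(1)))
  for (q in seq_along(frames)) {
    if (nrow(frames[[q]]$x) != n)
      problems <- c(problems, sprintf("frame %d: %d coordinates for %d atoms",
                                      q, nrow(frames[[q]]$x), n))
  }
  gb_ok <- all(is.finite(top$atoms$gb_radius) & is.finite(top$atoms$gb_screen))
  gb_any <- any(is.finite(top$atoms$gb_radius))
  if (gb_any && !gb_ok)
    problems <- c(problems, "GB parameters present for only a subset of atoms")
  if (!gb_any)
    notes <- c(notes, "no GB parameters: solvent stress term unavailable")
  if (!has_v)
    notes <- c(notes, "no velocities: kinetic stress term unavailable (potential-only stress)")
  if (!has_box)
    notes <- c(notes, "no box; per-atom carbon volume will be used")
  tms <- vapply(frames, function(f) f$time, numeric(1))
  if (length(tms) > 1 && any(diff(tms) <= 0))
    notes <- c(notes, "frame times are not strictly increasing")
  structure(list(
    counts = list(atoms = n, frames = length(frames), bonds = nrow(top$bonds),
                  angles = nrow(top$angles), dihedrals = nrow(top$dihedrals),
                  pairs14 = nrow(top$pairs14), exclusions = nrow(top$exclusions)),
    has_velocities = has_v, has_box = has_box, gb_complete = gb_ok,
    notes = notes, problems = problems), class = "system_report")
}

#' @export
print.system_report <- function(x, ...) {
  cat(sprintf("System: %d atoms, %d frames (velocities: %s, box: %s, GB: %s)\n",
              x$counts$atoms, x$counts$frames,
              if (x$has_velocities) "yes" else "no",
              if (x$has_box) "yes" else "no",
              if (x$gb_complete) "complete" else "incomplete"))
  cat(sprintf("  terms: %d bonds, %d angles, %d dihedrals, %d 1-4 pairs, %d exclusions\n",
              x$counts$bonds, x$counts$angles, x$counts$dihedrals,
              x$counts$pairs14, x$counts$exclusions))
  for (s in x$notes) cat("  note: ", s, "\n", sep = "")
  for (s in x$problems) cat("  PROBLEM: ", s, "\n", sep = "")
  invisible(x)
}
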