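test_that("characteristic volumes: uniform box share, carbon fallback, conservation", {
  top <- fftop(atom_df(27))
  fr <- mdframe(matrix(runif(81, 0, 3), 27, 3), box = c(3, 3, 3))
  v <- characteristic_volumes(top, fr)
  expect_equal(v$policy, "box_uniform")
  expect_equal(v$v, rep(1, 27))
  expect_equal(sum(v$v), prod(fr$box), tolerance = 1e-15)

  v2 <- characteristic_volumes(top, mdframe(fr$x))
  expect_equal(v2$policy, "carbon_default")
  expect_equal(v2$v, rep(0.0206, 27))
})

test_that("pair enumeration: cutoff on nonbonded only, bonded pairs always kept", {
  top <- fftop(atom_df(2), bonds = data.frame(i = 1, j = 2, kb = 10, b0 = 1.0))
  fr <- mdframe(rbind(c(0, 0, 0), c(1.2, 0, 0)))
  pr <- enumerate_pairs(fr, top, stress_options(cutoff = 1.0))
  expect_equal(nrow(pr$nonbonded), 0)
  expect_equal(nrow(pr$bond), 1)

  # nonbonded = brute-force O(N^2) enumeration minus exclusions
  set.seed(3)
  top10 <- fftop(atom_df(10), exclusions = data.frame(i = c(1, 2), j = c(4, 7)))
  x <- matrix(runif(30, 0, 1.5), 10, 3)
  pr <- enumerate_pairs(mdframe(x), top10, stress_options(cutoff = 0.8))
  ref <- NULL
  for (i in 1:9) for (j in (i + 1):10) {
    if (sqrt(sum((x[i, ] - x[j, ])^2)) <= 0.8 &&
        !(paste(i, j) %in% c("1 4", "2 7")))
      ref <- rbind(ref, c(i, j))
  }
  norm <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  expect_equal(norm(pr$nonbonded), norm(ref), ignore_attr = TRUE)
})

test_that("cell-list and brute-force pair enumeration agree, open and periodic", {
  set.seed(8)
  x <- matrix(runif(900, 0, 4), 300, 3)
  key <- function(p) sort(paste(p[, 1], p[, 2]))
  for (box in list(numeric(0), c(4, 4, 4))) {
    brute <- atomstress:::.cpp_nb_pairs(x, 1.0, box, 1000L)   # brute path (n < limit)
    cell <- atomstress:::.cpp_nb_pairs(x, 1.0, box, 10L)      # cell-list path
    expect_identical(key(brute), key(cell))
    expect_gt(nrow(brute), 0)
  }
})

test_that("cutoff beyond half the box edge is rejected", {
  top <- fftop(atom_df(8))
  fr <- mdframe(matrix(runif(24, 0, 1.8), 8, 3), box = c(1.8, 1.8, 1.8))
  expect_error(frame_atom_stress(fr, top, stress_options(cutoff = 1.0)),
               "half the shortest box edge")
  expect_silent(frame_atom_stress(fr, top, stress_options(cutoff = 0.89)))
})

test_that("stretched bond gives tensile stress (+332.1 bar) and negative pressure", {
  e <- build_test_structures()$bond_stretched
  st <- frame_atom_stress(mdframe(e$x), e$top, stress_options(carbon_volume = 0.02))
  expect_equal(st$bond, rep(20 * 16.6054e-3, 2), tolerance = 1e-12)
  expect_equal(st$total, st$bond, tolerance = 1e-15)
  expect_equal(st$hydrostatic_pressure, -st$total)
  # compressed bond: positive pressure
  xc <- rbind(c(0, 0, 0), c(0.08, 0, 0))
  stc <- frame_atom_stress(mdframe(xc), e$top, stress_options(carbon_volume = 0.02))
  expect_true(all(stc$hydrostatic_pressure > 0))
})

test_that("stress vanishes for every term at an isolated energy minimum", {
  cats <- build_test_structures()
  for (nm in c("bond_eq", "torsion_stationary", "lj_pair_min")) {
    st <- frame_atom_stress(mdframe(cats[[nm]]$x), cats[[nm]]$top)
    expect_lt(max(abs(st$total)), 1e-7, label = nm)
  }
})

test_that("fixture manifests: expected zero and nonzero terms", {
  cats <- build_test_structures()
  for (nm in names(cats)) {
    e <- cats[[nm]]
    st <- frame_atom_stress(mdframe(e$x), e$top)
    for (term in setdiff(e$expect$zero, "kinetic"))
      expect_lt(max(abs(st[[term]])), 1e-7, label = paste(nm, term))
    for (term in e$expect$nonzero)
      expect_gt(max(abs(st[[term]])), 1e-6, label = paste(nm, term))
  }
})

test_that("mean principal stress is invariant under rigid rotation (1e-9)", {
  e <- build_test_structures()$combined5
  st1 <- frame_atom_stress(mdframe(e$x), e$top)
  st2 <- frame_atom_stress(mdframe(rigid_rotate(e$x)), e$top)
  for (cl in c("bond", "angle", "dihedral", "coulomb", "vdw", "gb", "total"))
    expect_lt(relerr(st2[[cl]], st1[[cl]], floor = max(abs(st1$total))), 1e-9,
              label = cl)
})

test_that("trace additivity and the volume scaling law hold exactly", {
  e <- build_test_structures()$combined5
  st <- frame_atom_stress(mdframe(e$x), e$top)
  lhs <- st$bond + st$angle + st$dihedral + st$coulomb + st$vdw + st$gb + st$kinetic
  expect_equal(st$total, lhs, tolerance = 1e-14)
  st2 <- frame_atom_stress(mdframe(e$x), e$top,
                           stress_options(carbon_volume = 2 * 0.0206))
  expect_equal(st2$total, st$total / 2, tolerance = 1e-14)
})

test_that("results are independent of atom ordering in the topology", {
  e <- build_test_structures()$combined5
  st <- frame_atom_stress(mdframe(e$x), e$top)
  set.seed(2)
  perm <- sample(5)
  inv <- order(perm)
  at <- e$top$atoms[perm, ]
  rownames(at) <- NULL
  remap <- function(df, cols) {
    for (cl in cols) df[[cl]] <- inv[df[[cl]]]
    df
  }
  ptop <- fftop(at, remap(e$top$bonds, c("i", "j")),
                remap(e$top$angles, c("i", "j", "k")),
                remap(e$top$dihedrals, c("i", "j", "k", "l")),
                remap(e$top$pairs14, c("i", "j")),
                remap(e$top$exclusions, c("i", "j")))
  stp <- frame_atom_stress(mdframe(e$x[perm, ]), ptop)
  expect_equal(stp$total[inv], st$total, tolerance = 1e-10)
})

test_that("kinetic stress: zeros, closed-form value, compressive sign", {
  top <- fftop(atom_df(1, mass = 12))
  vols <- list(v = 1, policy = "box_uniform")
  fr0 <- mdframe(matrix(0, 1, 3), v = matrix(0, 1, 3))
  expect_equal(kinetic_stress(fr0, top, vols), 0)
  fr <- mdframe(matrix(0, 1, 3), v = matrix(c(1, 0, 0), 1, 3))
  # -m v^2 / (3 V) = -4 kJ/mol/nm^3 = -66.4216 bar
  expect_equal(kinetic_stress(fr, top, vols), -4 * 16.6054e-3, tolerance = 1e-12)
  expect_error(kinetic_stress(mdframe(matrix(0, 1, 3)), top, vols),
               "no velocities")
})

test_that("ideal-gas mean pressure recovers N kT / V within 3 SEM", {
  set.seed(14)
  n <- 64; L <- 4; Tset <- 250
  top <- fftop(atom_df(n, mass = 39.948, epsilon = 0, charge = 0))
  x <- matrix(runif(3 * n, 0, L), n, 3)
  nfr <- 400
  pbar <- numeric(nfr)
  for (q in seq_len(nfr)) {
    v <- matrix(rnorm(3 * n), n, 3) * sqrt(0.0083144621 * Tset / 39.948)
    fr <- mdframe(x, v = v, box = c(L, L, L))
    st <- frame_atom_stress(fr, top, stress_options(include_kinetic = TRUE))
    pbar[q] <- mean(st$hydrostatic_pressure)
  }
  expected <- n * 0.0083144621 * Tset / L^3 * 16.6054e-3  # kbar
  sem <- sd(pbar) / sqrt(nfr)
  expect_lt(abs(mean(pbar) - expected), 3 * sem + 1e-12)
  expect_gt(mean(pbar), 0)  # ideal gas: compression
})

test_that("mean hydrostatic pressure equals the independent virial formula per frame", {
  set.seed(7)
  n <- 100; L <- 5; Tset <- 300
  top <- fftop(atom_df(n, mass = 39.948, sigma = 0.34, epsilon = 0.996))
  x <- matrix(runif(3 * n, 0, L), n, 3)
  for (it in 1:300) {
    pr <- atomstress:::.cpp_nb_pairs(x, 0.25, c(L, L, L), 1000L)
    if (nrow(pr) == 0) break
    for (q in seq_len(nrow(pr))) x[pr[q, 1], ] <- runif(3, 0, L)
  }
  for (rep in 1:3) {
    v <- matrix(rnorm(3 * n), n, 3) * sqrt(0.0083144621 * Tset / 39.948)
    fr <- mdframe(x, v = v, box = c(L, L, L))
    st <- frame_atom_stress(fr, top, stress_options(include_kinetic = TRUE))
    # independent virial-pressure evaluation from the closed-form LJ derivative
    pr <- atomstress:::.cpp_nb_pairs(x, 1.0, c(L, L, L), 1000L)
    W <- 0
    for (q in seq_len(nrow(pr))) {
      d <- x[pr[q, 1], ] - x[pr[q, 2], ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d * d))
      sr6 <- (0.34 / r)^6
      W <- W + (24 * 0.996 / r) * (2 * sr6 * sr6 - sr6) * r
    }
    K <- sum(0.5 * 39.948 * rowSums(v * v))
    P <- (2 * K / 3 + W / 3) / L^3 * 16.6054e-3  # kbar
    expect_lt(abs(mean(st$hydrostatic_pressure) - P) / abs(P), 1e-6)
    x <- x + 0.01 * matrix(rnorm(3 * n), n, 3)  # jiggle for the next frame
  }
})

test_that("compiled per-frame virials agree with the R pairwise decomposition", {
  cats <- build_test_structures()
  for (nm in c("combined5", "angle_bent", "torsion_generic")) {
    e <- cats[[nm]]
    top <- e$top
    st <- frame_atom_stress(mdframe(e$x), top, stress_options(gb = FALSE))
    n <- n_atoms(top)
    acc <- matrix(0, n, 5,
                  dimnames = list(NULL, c("bond", "angle", "dihedral",
                                          "coulomb", "vdw")))
    add <- function(acc, pf, col) {
      for (q in seq_len(nrow(pf))) {
        d <- e$x[pf$j[q], ] - e$x[pf$i[q], ]
        val <- sum(d * as.numeric(pf[q, c("fx", "fy", "fz")]))
        acc[pf$i[q], col] <- acc[pf$i[q], col] + val
        acc[pf$j[q], col] <- acc[pf$j[q], col] + val
      }
      acc
    }
    b <- top$bonds
    for (q in seq_len(nrow(b))) {
      g <- pair_geometry(e$x[b$i[q], ], e$x[b$j[q], ])
      acc <- add(acc, bond_pair_force(g, b$kb[q], b$b0[q], b$i[q], b$j[q]), "bond")
    }
    a <- top$angles
    for (q in seq_len(nrow(a)))
      acc <- add(acc, angle_pairwise_forces(e$x[a$i[q], ], e$x[a$j[q], ],
                                            e$x[a$k[q], ], a$ktheta[q],
                                            a$theta0[q],
                                            c(a$i[q], a$j[q], a$k[q])), "angle")
    dh <- top$dihedrals
    for (q in seq_len(nrow(dh)))
      acc <- add(acc, dihedral_pairwise_forces(e$x[dh$i[q], ], e$x[dh$j[q], ],
                                               e$x[dh$k[q], ], e$x[dh$l[q], ],
                                               dh$kphi[q], dh$mult[q],
                                               dh$phase[q],
                                               c(dh$i[q], dh$j[q], dh$k[q],
                                                 dh$l[q])), "dihedral")
    pr <- enumerate_pairs(mdframe(e$x), top, stress_options())
    at <- top$atoms
    nbf <- function(i, j, qs, ls) {
      g <- pair_geometry(e$x[i, ], e$x[j, ])
      rbind(coulomb_pair_force(g, at$charge[i], at$charge[j], qs, i, j),
            lj_pair_force(g, (at$sigma[i] + at$sigma[j]) / 2,
                          sqrt(at$epsilon[i] * at$epsilon[j]), ls, i, j))
    }
    for (q in seq_len(nrow(pr$nonbonded))) {
      pf2 <- nbf(pr$nonbonded[q, 1], pr$nonbonded[q, 2], 1, 1)
      acc <- add(acc, pf2[1, ], "coulomb")
      acc <- add(acc, pf2[2, ], "vdw")
    }
    p14 <- top$pairs14
    for (q in seq_len(nrow(p14))) {
      pf2 <- nbf(p14$i[q], p14$j[q], p14$qscale[q], p14$ljscale[q])
      acc <- add(acc, pf2[1, ], "coulomb")
      acc <- add(acc, pf2[2, ], "vdw")
    }
    vols <- characteristic_volumes(top, mdframe(e$x), stress_options())
    ref <- acc * 16.6054e-3 / (6 * vols$v)
    for (cl in colnames(acc))
      expect_lt(relerr(st[[cl]], ref[, cl], floor = max(abs(ref), 1e-8)), 1e-9,
                label = paste(nm, cl))
  }
})

test_that("atom_stress over a trajectory annotates frame errors and respects selection", {
  e <- build_test_structures()$bond_stretched
  frames <- list(mdframe(e$x, 0), mdframe(e$x * 1.01, 1))
  df <- atom_stress(e$top, frames, stress_options(selection = 2L,
                                                  carbon_volume = 0.02))
  expect_equal(unique(df$atom), 2L)
  expect_equal(nrow(df), 2)
  bad <- list(mdframe(e$x, 0), mdframe(rbind(c(0, 0, 0), c(0, 0, 0)), 1))
  expect_error(atom_stress(e$top, bad), "frame 2.*degenerate")
})
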