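test_that("the validation catalog is deterministic and seed-free", {
  a <- build_test_structures()
  b <- build_test_structures()
  expect_identical(a, b)
  expect_true(all(c("bond_eq", "bond_stretched", "angle_bent",
                    "torsion_stationary", "torsion_generic", "charged_pair",
                    "lj_pair_min", "lj_pair_off", "combined5") %in% names(a)))
})

test_that("the numerical force oracle matches analytic expectations", {
  cats <- build_test_structures()
  # zero-interaction system
  top0 <- fftop(atom_df(2, epsilon = 0, charge = 0))
  expect_equal(numerical_force_oracle(top0, rbind(c(0, 0, 0), c(0.3, 0, 0))),
               matrix(0, 2, 3), tolerance = 1e-9)
  # stretched diatomic: (+/-20, 0, 0)
  fo <- numerical_force_oracle(cats$bond_stretched$top, cats$bond_stretched$x)
  expect_equal(fo, rbind(c(20, 0, 0), c(-20, 0, 0)), tolerance = 1e-6)
  # agreement with the compiled analytic forces on every catalog entry
  for (nm in names(cats)) {
    e <- cats[[nm]]
    fo <- numerical_force_oracle(e$top, e$x)
    res <- atomstress:::.cpp_forces(e$x, atomstress:::.top_cpp(e$top), Inf,
                                    numeric(0), 200L)
    fg <- matrix(0, nrow(e$x), 3)
    if (all(is.finite(e$top$atoms$gb_radius)) && any(e$top$atoms$charge != 0))
      fg <- sum_pair_forces(gb_pair_forces(e$x, e$top$atoms), nrow(e$x))
    expect_lt(relerr(res$forces + fg, fo, floor = max(abs(fo), 1)), 1e-6,
              label = nm)
  }
})

test_that("graphene ribbons have exact bond lengths and honeycomb coordination", {
  for (edge in c("armchair", "zigzag")) {
    sp <- graphene_spec(edge_type = edge, width = 2.5, length = 3)
    st <- build_graphene(sp)
    b <- st$top$bonds
    bl <- sqrt(rowSums((st$x[b$i, ] - st$x[b$j, ])^2))
    expect_lt(max(abs(bl - sp$bond_length)), 1e-12)
    deg <- tabulate(c(b$i, b$j), n_atoms(st$top))
    expect_true(all(deg >= 2))
    expect_true(any(deg == 3))
    # angle count equals the graph-combinatorial sum over vertices of C(deg, 2)
    expect_equal(nrow(st$top$angles), sum(choose(deg, 2)))
    # all charges zero
    expect_true(all(st$top$atoms$charge == 0))
  }
  expect_error(build_graphene(graphene_spec(width = 0.2, length = 0.2)),
               "too small")
})

test_that("graphene builder output is byte-stable across calls", {
  a <- build_graphene(graphene_spec(width = 2, length = 2))
  b <- build_graphene(graphene_spec(width = 2, length = 2))
  expect_identical(a$x, b$x)
  expect_identical(a$top, b$top)
})

test_that("nanotubes have no under-coordinated atoms along the wrapped direction", {
  st <- build_nanotube(graphene_spec(edge_type = "zigzag", width = 2.5, length = 2.5))
  b <- st$top$bonds
  deg <- tabulate(c(b$i, b$j), n_atoms(st$top))
  expect_true(all(deg >= 2))
  # atoms away from the open tube ends are fully 3-coordinated
  y <- st$x[, 2]
  interior <- y > min(y) + 0.15 & y < max(y) - 0.15
  expect_true(all(deg[interior] == 3))
  # cross-section is a circle: radius constant
  r <- sqrt(st$x[, 1]^2 + st$x[, 3]^2)
  expect_lt(diff(range(r)), 1e-9)
})

test_that("velocity pulses convert km/s directly and leave other atoms untouched", {
  st <- build_graphene(graphene_spec(width = 2, length = 2))
  st$v <- matrix(1e-3, n_atoms(st$top), 3)
  sel <- 1:4
  st2 <- apply_velocity_pulse(st, sel, velocity = c(0, 0, 20.5))
  expect_equal(st2$v[1, ], c(0, 0, 20.5))   # 20.5 km/s = 20.5 nm/ps
  expect_identical(st2$v[-sel, ], st$v[-sel, ])
  # radial mode: velocities parallel to in-plane radial vectors
  ctr <- colMeans(st$x)
  st3 <- apply_velocity_pulse(st, sel, radial_speed = 5, center = ctr)
  for (i in sel) {
    d <- st3$x[i, ] - ctr; d[3] <- 0
    cr <- d[1] * st3$v[i, 2] - d[2] * st3$v[i, 1]
    expect_lt(abs(cr), 1e-10)
    expect_equal(sqrt(sum(st3$v[i, ]^2)), 5, tolerance = 1e-12)
  }
  expect_error(apply_velocity_pulse(st, integer(0), velocity = c(1, 0, 0)),
               "empty selection")
})

test_that("NVE integration: oscillator period, energy conservation, static minimum", {
  top <- build_test_structures()$bond_eq$top
  state <- structure(list(top = top, x = rbind(c(0, 0, 0), c(0.11, 0, 0)),
                          v = matrix(0, 2, 3), restraint_k = 0,
                          restraint_ref = NULL), class = "mini_md")
  mu <- 12.011 / 2
  period <- 2 * pi * sqrt(mu / 1000)
  dt <- period / 400
  fr <- nve_integrate(state, dt = dt, steps = 10000, stride = 1, cutoff = 3)
  en <- attr(fr, "energies")
  expect_lt(diff(range(en$etot)) / abs(mean(en$etot)), 1e-4)
  d <- vapply(fr, function(f) f$x[2, 1] - f$x[1, 1], numeric(1))
  t <- vapply(fr, function(f) f$time, numeric(1))
  peaks <- which(diff(sign(diff(d))) == -2) + 1
  expect_lt(abs(mean(diff(t[peaks])) - period) / period, 1e-3)

  # zero velocities at the minimum: static trajectory
  state$x <- rbind(c(0, 0, 0), c(0.1, 0, 0))
  fr0 <- nve_integrate(state, dt = dt, steps = 100, stride = 10, cutoff = 3)
  expect_equal(fr0[[length(fr0)]]$x, state$x, tolerance = 1e-12)
})

test_that("restraints steer the dynamics but never enter the stress", {
  st <- build_test_structures()$bond_stretched
  state <- structure(list(top = st$top, x = st$x, v = matrix(0, 2, 3),
                          restraint_k = 500, restraint_ref = st$x),
                     class = "mini_md")
  fr <- nve_integrate(state, dt = 1e-4, steps = 10, stride = 10)
  s1 <- frame_atom_stress(fr[[2]], st$top, stress_options(carbon_volume = 0.02))
  state$restraint_k <- 0
  fr2 <- nve_integrate(state, dt = 1e-4, steps = 10, stride = 10)
  s2 <- frame_atom_stress(fr2[[2]], st$top, stress_options(carbon_volume = 0.02))
  # trajectories differ (restraint acts on motion)...
  expect_false(isTRUE(all.equal(fr[[2]]$x, fr2[[2]]$x, tolerance = 1e-12)))
  # ...but the stress of a given frame depends only on coordinates
  s1b <- frame_atom_stress(mdframe(fr[[2]]$x), st$top,
                           stress_options(carbon_volume = 0.02))
  expect_equal(s1$total, s1b$total, tolerance = 1e-14)
})

test_that("FIRE minimization drives the maximum force below tolerance", {
  st <- build_graphene(graphene_spec(width = 2, length = 2))
  st2 <- minimize_energy(st, cutoff = 1.0, max_steps = 5000, ftol = 1.0)
  expect_lt(attr(st2, "fmax"), 1.0)
  f <- atomstress:::.cpp_forces(st2$x, atomstress:::.top_cpp(st2$top), 1.0,
                                numeric(0), 200L)
  expect_lt(max(abs(f$forces)), 1.0)
})

test_that("wavefront speed: constructed front, threshold robustness, static error", {
  # synthetic stress field with a front moving at exactly 10 nm/ps: atoms on
  # exact radial rings so the detected front radius is noise-free
  rings <- seq(0, 10, by = 0.5)
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  xy <- do.call(rbind, lapply(rings, function(rr) cbind(rr * cos(ang),
                                                        rr * sin(ang), 0)))
  r <- sqrt(rowSums(xy[, 1:2]^2))
  frames <- lapply(0:10, function(k) mdframe(xy, time = k * 0.05))
  stress <- do.call(rbind, lapply(1:11, function(q) {
    t <- (q - 1) * 0.05
    data.frame(frame = q, atom = seq_along(r),
               total = ifelse(r <= 10 * t + 1e-9, 2.5, 0))
  }))
  w <- measure_wavefront_speed(frames, c(0, 0, 0), "tensile-front",
                               stress = stress)
  expect_equal(w$speed_km_s, 10, tolerance = 1e-9)
  expect_equal(w$r_squared, 1, tolerance = 1e-12)
  w2 <- measure_wavefront_speed(frames, c(0, 0, 0), "tensile-front",
                                stress = stress, threshold = 0.2)
  w3 <- measure_wavefront_speed(frames, c(0, 0, 0), "tensile-front",
                                stress = stress, threshold = 0.3)
  expect_lt(abs(w2$speed_km_s - w3$speed_km_s) / w2$speed_km_s, 0.05)

  # transverse mode on a displaced plateau: slope recovered to a few percent
  # (the out-of-plane offset enters the 3D radius)
  framesz <- lapply(0:10, function(k) {
    z <- ifelse(r <= 10 * k * 0.05 + 1e-9, 0.05, 0)
    mdframe(cbind(xy[, 1:2], z), time = k * 0.05)
  })
  wt <- measure_wavefront_speed(framesz, c(0, 0, 0), "transverse-displacement")
  expect_equal(wt$speed_km_s, 10, tolerance = 0.02)

  # static field: no detectable front
  static <- lapply(0:10, function(k) mdframe(xy, time = k * 0.05))
  expect_error(measure_wavefront_speed(static, c(0, 0, 0),
                                       "transverse-displacement"),
               "no detectable front")
})
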