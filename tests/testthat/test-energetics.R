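test_that("bending energy: flat zero, sphere 8*pi*kappa, matched spontaneous curvature", {
  f <- fix_flat(6)
  gf <- vertex_geometry(f)
  expect_equal(as.numeric(bending_energy(f, gf, membrane_params(kappa = 20))), 0)
  s <- fix_sphere(3)
  g <- vertex_geometry(s)
  R <- sphere_radius(s)
  eb <- bending_energy(s, g, membrane_params(kappa = 20, kappa_G = 0))
  expect_lt(abs(as.numeric(eb) / (8 * pi * 20) - 1), 0.03)
  # spontaneous curvature matched to the sphere: energy collapses
  ebm <- bending_energy(s, g, membrane_params(kappa = 20, C_bar = 2 / R))
  expect_lt(abs(as.numeric(ebm)), 0.03 * 8 * pi * 20)
  # Gaussian term: positive kappa_G lowers a sphere's energy by 4*pi*kappa_G
  ebg <- bending_energy(s, g, membrane_params(kappa = 20, kappa_G = 10))
  expect_equal(as.numeric(eb) - as.numeric(ebg), 10 * 4 * pi, tolerance = 0.01)
})

test_that("Gaussian term is topological across deformations of fixed topology", {
  s <- build_icosphere(2)
  g0 <- vertex_geometry(s)
  gauss0 <- -sum(g0$c1 * g0$c2 * g0$area)
  # squash into a spheroid (same topology, different shape)
  s2 <- s
  s2$vertices[, 3] <- s2$vertices[, 3] * 0.6
  g2 <- vertex_geometry(s2)
  gauss2 <- -sum(g2$c1 * g2$c2 * g2$area)
  expect_lt(abs(gauss0 / (-4 * pi) - 1), 0.01)
  expect_lt(abs(gauss2 / (-4 * pi) - 1), 0.02)
})

test_that("area coupling energy evaluates the harmonic constraint", {
  s <- fix_sphere(2)
  A <- sum(triangle_geometry(s)$area)
  # A = 1.1 A_0, K_A = 100, N_T = 320 -> 320 * 50 * 0.01 = 160 kBT
  expect_equal(area_coupling_energy(s, K_A = 100, A_0 = A / 1.1), 160,
               tolerance = 1e-10)
  expect_equal(area_coupling_energy(s, K_A = 100, A_0 = A), 0)
  expect_equal(area_coupling_energy(s, K_A = 0, A_0 = A / 2), 0)
  expect_error(area_coupling_energy(s, K_A = 100, A_0 = -1), "positive")
})

test_that("enclosed volume matches the analytic sphere and flips with orientation", {
  s <- fix_sphere(3)
  R <- sphere_radius(s)
  V <- enclosed_volume(s)
  expect_lt(abs(V / (4 / 3 * pi * R^3) - 1), 0.01)
  inv <- s
  inv$triangles <- inv$triangles[, c(1, 3, 2)]
  expect_equal(enclosed_volume(inv), -V)
  expect_error(enclosed_volume(fix_flat(4)), "periodic")
})

test_that("volume coupling: null cases and direct evaluation", {
  s <- fix_sphere(2)
  A <- sum(triangle_geometry(s)$area)
  V <- enclosed_volume(s)
  V0 <- A^1.5 / (6 * sqrt(pi))
  expect_equal(volume_coupling_energy(V0, A, dP = 0, K = 500, v_t = 1), 0)
  expect_equal(volume_coupling_energy(V, A, dP = 0, K = 0), 0)
  expect_equal(volume_coupling_energy(0.5 * V0, A, dP = 0, K = 1000, v_t = 1), 125)
  # numerically minimized at V = v_t V0
  vs <- seq(0.5, 1, 0.01) * V0
  es <- vapply(vs, volume_coupling_energy, 0, A = A, dP = 0, K = 1000, v_t = 0.7)
  expect_equal(vs[which.min(es)] / V0, 0.7, tolerance = 0.011)
})

test_that("osmotic energy: null cases and equal-concentration stationary point", {
  expect_equal(osmotic_energy(3, RT = 1, c_in = 2, c_out = 1, V_ini = 3), 0)
  expect_equal(osmotic_energy(5, RT = 1, c_in = 0, c_out = 0, V_ini = 3), 0)
  # dE/dV = 0 where c_in V_ini / V = c_out
  Vstar <- 2 * 3 / 1.5 # c_in V_ini / c_out
  vs <- seq(0.5 * Vstar, 1.5 * Vstar, length.out = 401)
  es <- vapply(vs, osmotic_energy, 0, RT = 1.2, c_in = 2, c_out = 1.5, V_ini = 3)
  expect_equal(vs[which.min(es)], Vstar, tolerance = 0.01)
  expect_error(osmotic_energy(-1, 1, 1, 1, 1), "positive")
})

test_that("global curvature energy: sphere-matched target and null cases", {
  s <- fix_sphere(3)
  g <- vertex_geometry(s)
  R <- sphere_radius(s)
  e0 <- global_curvature_energy(s, g, k_r = 10, m_0 = 2 / R)
  # M = (2/R) A for a sphere, so the term nearly vanishes
  expect_lt(e0, 0.01 * 10 * g$total_area * (2 / R)^2)
  expect_equal(global_curvature_energy(s, g, k_r = 0, m_0 = 1), 0)
  f <- fix_flat(6)
  gf <- vertex_geometry(f)
  expect_equal(global_curvature_energy(f, gf, k_r = 5, m_0 = 0), 0)
  expect_equal(global_curvature_energy(f, gf, k_r = 5, m_0 = 0.3),
               5 / 2 * gf$total_area * 0.3^2)
})

test_that("frame tension energy is -tau * Ap and prefers larger frames", {
  b <- dts_box(c(20, 20, 30), periodic = c(TRUE, TRUE, FALSE))
  expect_equal(frame_tension_energy(b, 0), 0)
  expect_equal(frame_tension_energy(b, 2), -800)
  b2 <- b; b2$L[1] <- 25
  expect_lt(frame_tension_energy(b2, 2), frame_tension_energy(b, 2))
  expect_error(frame_tension_energy(dts_box(c(1, 1, 1)), 1), "periodic")
})

test_that("total energy sums enabled terms and is extensive", {
  f <- fix_flat(6)
  st <- simulation_state(f, membrane_params(kappa = 20))
  expect_equal(as.numeric(total_energy(st)), 0)
  # two disjoint identical vesicles have twice the energy of one
  s <- build_icosphere(2)
  st1 <- simulation_state(s, membrane_params(kappa = 15))
  two <- s
  shifted <- s$vertices
  shifted[, 1] <- shifted[, 1] + 10 * sphere_radius(s)
  two$vertices <- rbind(s$vertices, shifted)
  two$triangles <- rbind(s$triangles, s$triangles + nrow(s$vertices))
  two$domain <- c(s$domain, s$domain)
  two$box$L <- two$box$L * 20
  st2 <- simulation_state(two, membrane_params(kappa = 15))
  expect_equal(as.numeric(total_energy(st2)), 2 * as.numeric(total_energy(st1)),
               tolerance = 1e-8)
})

test_that("incremental engine bookkeeping matches a full recomputation", {
  set.seed(21)
  m <- build_flat_grid(6, 6, 1.25)
  ty <- list(inclusion_type("a", "type1", c0 = 0.3))
  incl <- place_inclusions(m, ty, 0.2, list(pair_potential("a", "a", A = 0.4, B = 0.2, n = 2)))
  st <- simulation_state(m, membrane_params(kappa = 20),
                         ensemble_couplings(tension = list(tau = 0.5)),
                         inclusions = incl)
  # run with no mid-run resynchronization: the last recorded energy is the
  # purely incremental total after ~10^3 accepted moves
  r <- run_mc(st, 400, record_every = 400, resync_every = 0, seed = 8)
  e_inc <- r$observables$energy[nrow(r$observables)]
  e_full <- as.numeric(total_energy(r$state))
  expect_equal(e_inc, e_full, tolerance = 1e-8)
})
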