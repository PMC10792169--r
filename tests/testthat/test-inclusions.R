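test_that("type-1 site energy: null cases and direct evaluation", {
  ty0 <- inclusion_type("x", "type1")
  expect_equal(type1_site_energy(H = 0.3, K = 0.05, A_v = 1.2, ty0, kappa = 20), 0)
  ty <- inclusion_type("x", "type1", c0 = 0.4)
  expect_equal(type1_site_energy(H = 0, K = 0, A_v = 1, ty, kappa = 20), 0)
  # dkappa = dkappa_G = 0, c0 = 0.4, kappa = 20, 2H = 0.4, A = 1:
  # -2 * 20 * 0.4 * 0.2 = -3.2 kBT
  expect_equal(type1_site_energy(H = 0.2, K = 0, A_v = 1, ty, kappa = 20), -3.2)
})

test_that("type-2 site energy follows the directional curvature mismatch", {
  m <- fix_tube()
  rho <- 1.25 / (2 * sin(pi / 12))
  g <- vertex_geometry(m)
  v <- 30L
  circ <- g$T1[v, ] # circumferential on a tube (c1 direction)
  axial <- g$T2[v, ]
  ty <- inclusion_type("bar", "type2", k1 = 10, C_par0 = 1 / rho, k2 = 0)
  # matched curvature: circumferential inclusion on the matching cylinder
  expect_lt(type2_site_energy(g, v, circ, ty),
            0.01 * 10 / 2 * (1 / rho)^2 * g$area[v])
  # axial inclusion sees C_par = c2 ~ 0: e = k1/2 * C_par0^2 * A
  e_ax <- type2_site_energy(g, v, axial, ty)
  expect_equal(e_ax, 10 / 2 * (0 - 1 / rho)^2 * g$area[v], tolerance = 0.1 * e_ax)
  # unit-scale check: k1 = 10, C_par0 = 1, flat direction, A = 1 -> 5 kBT
  gg <- list(c1 = 0, c2 = 0, T1 = matrix(c(1, 0, 0), 1), T2 = matrix(c(0, 1, 0), 1),
             area = 1)
  ty1 <- inclusion_type("bar", "type2", k1 = 10, C_par0 = 1)
  expect_equal(type2_site_energy(gg, 1L, c(1, 0, 0), ty1), 5)
  # flat vertex with zero preferred curvatures: zero for any orientation
  ty2 <- inclusion_type("b2", "type2", k1 = 10, k2 = 4)
  expect_equal(type2_site_energy(gg, 1L, c(0.6, 0.8, 0), ty2), 0)
})

test_that("type-2 energy has nematic symmetry", {
  s <- fix_sphere(2)
  g <- vertex_geometry(s)
  ty <- inclusion_type("bar", "type2", k1 = 10, k2 = 3, C_par0 = 0.5, C_perp0 = 0.1)
  set.seed(2)
  for (v in sample.int(nrow(s$vertices), 5)) {
    th <- runif(1, 0, 2 * pi)
    d <- cos(th) * g$T1[v, ] + sin(th) * g$T2[v, ]
    expect_equal(type2_site_energy(g, v, d, ty),
                 type2_site_energy(g, v, -d, ty), tolerance = 1e-12)
  }
})

test_that("pair energy: minimum, symmetry, and periodicity", {
  pot <- pair_potential("a", "a", A = 1, B = 2, C = 3, n = 2,
                        Theta0 = 0.3, gamma0 = 0.1)
  expect_equal(pair_energy(0.3, 0.1, pot), -6) # global minimum -A-B-C
  p0 <- pair_potential("a", "a")
  expect_equal(pair_energy(1.1, 0.5, p0), 0)
  # Fig-7D-style dimerization term: A = B = 0, C = 20, gamma0 = pi/4
  pd <- pair_potential("a", "a", C = 20, gamma0 = pi / 4)
  gs <- seq(-pi, pi, length.out = 721)
  es <- pair_energy(0, gs, pd)
  expect_equal(gs[which.min(es)], pi / 4, tolerance = 0.01)
  expect_equal(min(es), -20, tolerance = 1e-12)
  # n = 2: period pi in Theta
  th <- seq(-pi, pi, 0.37)
  expect_equal(pair_energy(th, 0, pot), pair_energy(th + pi, 0, pot))
  # exchange symmetry: Theta -> -Theta with even n
  expect_equal(pair_energy(th, 0.2, pot), pair_energy(-th + 0.6, 0.2, pot))
})

test_that("inclusion field energy counts sites and unique adjacent pairs", {
  s <- build_icosphere(1)
  g <- vertex_geometry(s)
  ty <- list(inclusion_type("a", "type1", c0 = 0.2))
  pots <- list(pair_potential("a", "a", A = 1))
  mk <- function(hosts) {
    incl <- dts_inclusions(hosts, rep(1L, length(hosts)),
                           g$T1[hosts, , drop = FALSE], ty, pots)
    simulation_state(s, membrane_params(kappa = 20), inclusions = incl)
  }
  expect_equal(inclusion_field_energy(simulation_state(s, membrane_params())), 0)
  # two isolated inclusions: site terms only
  ring1 <- one_ring(s, 1L)
  far <- setdiff(seq_len(nrow(s$vertices)), c(1L, ring1))[1]
  e_iso <- inclusion_field_energy(mk(c(1L, far)), g)
  site <- function(v) {
    H <- (g$c1[v] + g$c2[v]) / 2
    type1_site_energy(H, g$c1[v] * g$c2[v], g$area[v], ty[[1]], 20)
  }
  expect_equal(e_iso, site(1L) + site(far), tolerance = 1e-12)
  # a triangle of three mutually adjacent inclusions has exactly 3 pair terms
  tri <- s$triangles[1, ]
  e_tri <- inclusion_field_energy(mk(tri), g)
  expect_equal(e_tri, sum(vapply(tri, site, 0)) - 3 * 1, tolerance = 1e-12)
})

test_that("occupancy exclusion: never two inclusions on one vertex", {
  expect_error(dts_inclusions(c(3L, 3L), c(1L, 1L), matrix(0, 2, 3),
                              list(inclusion_type("a", "type1"))),
               "one inclusion")
  # after many sweeps with hops, hosts remain unique
  set.seed(5)
  m <- fix_flat(6)
  ty <- list(inclusion_type("a", "type1", c0 = 0.4))
  incl <- place_inclusions(m, ty, 0.3, list(pair_potential("a", "a", A = 0.5)))
  st <- simulation_state(m, membrane_params(kappa = 20), inclusions = incl)
  r <- run_mc(st, 300, seed = 17)
  expect_equal(anyDuplicated(r$state$inclusions$vertex), 0)
})
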