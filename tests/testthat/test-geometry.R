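test_that("sphere principal curvatures match 1/R with outward-positive sign", {
  m <- fix_sphere(3)
  R <- sphere_radius(m)
  g <- vertex_geometry(m)
  expect_true(all(g$c1 > 0) && all(g$c2 > 0)) # convex, outward normals
  reg <- valences(m) == 6 # cone (5-valent) vertices carry concentrated
                          # polyhedral curvature; see the methods vignette
  H <- (g$c1 + g$c2) / 2
  expect_true(all(abs(H[reg] * R - 1) < 0.02))
  # the eigenvalue split at near-umbilic vertices is wider than the mean
  # (ordering c1 >= c2 repels the eigenvalues); both stay within 7%
  expect_true(all(abs(g$c1[reg] * R - 1) < 0.07))
  expect_true(all(abs(g$c2[reg] * R - 1) < 0.07))
  expect_lt(abs(sum(H * g$area) / sum(g$area) * R - 1), 0.02)
})

test_that("Gauss-Bonnet holds on closed fixtures", {
  g <- vertex_geometry(fix_sphere(3))
  expect_lt(abs(sum(g$c1 * g$c2 * g$area) / (4 * pi) - 1), 0.01)
  gt <- vertex_geometry(fix_torus())
  expect_lt(abs(sum(gt$c1 * gt$c2 * gt$area)) / (4 * pi), 0.05)
})

test_that("R reference geometry agrees with the compiled path", {
  m <- fix_sphere(2)
  g <- vertex_geometry(m)
  gr <- r_vertex_geometry(m, seq_len(nrow(m$vertices)), g)
  expect_equal(gr$area, g$area, tolerance = 1e-10)
  expect_equal(gr$c1, g$c1, tolerance = 1e-8)
  expect_equal(gr$c2, g$c2, tolerance = 1e-8)
  expect_equal(gr$normal, g$normal, tolerance = 1e-10)
})

test_that("refresh_region updates exactly the dependency region", {
  m <- fix_flat(6)
  g0 <- vertex_geometry(m)
  # move one interior vertex
  v <- 15L
  m$vertices[v, 3] <- m$vertices[v, 3] + 0.4
  g_inc <- refresh_region(m, g0, v)
  expect_equal(length(attr(g_inc, "refreshed")), 1 + length(one_ring(m, v)))
  g_full <- r_vertex_geometry(m, seq_len(nrow(m$vertices)), g0)
  expect_equal(g_inc$area, g_full$area, tolerance = 1e-12)
  expect_equal(g_inc$c1, g_full$c1, tolerance = 1e-12)
  expect_equal(g_inc$c2, g_full$c2, tolerance = 1e-12)
  expect_equal(g_inc$normal, g_full$normal, tolerance = 1e-12)
  expect_equal(g_inc$T1, g_full$T1, tolerance = 1e-12)
  # empty set is a no-op
  g_same <- refresh_region(m, g_inc, integer(0))
  expect_identical(attr(g_same, "refreshed"), integer(0))
})

test_that("Euler's curvature formula obeys the trace identity", {
  set.seed(4)
  c1 <- rnorm(50); c2 <- rnorm(50); th <- runif(50, -pi, pi)
  dc <- euler_directional_curvatures(c1, c2, th)
  expect_equal(dc$C_par + dc$C_perp, c1 + c2)
  d0 <- euler_directional_curvatures(c1, c2, 0)
  expect_equal(d0$C_par, c1)
  expect_equal(d0$C_perp, c2)
  d90 <- euler_directional_curvatures(c1, c2, pi / 2)
  expect_equal(d90$C_par, c2)
  expect_equal(d90$C_perp, c1)
})

test_that("parallel transport preserves norms, inverts, and is trivial on flat sheets", {
  m <- fix_flat(6)
  g <- vertex_geometry(m)
  ring <- one_ring(m, 15L)
  vec <- c(0.6, 0.8, 0)
  out <- parallel_transport(m, g, 15L, ring[1], vec)
  expect_equal(out, vec, tolerance = 1e-12) # flat: identity on components
  # around a closed loop on the flat sheet: zero holonomy
  loop <- c(15L, ring[1], ring[2], 15L)
  v <- vec
  for (i in seq_len(length(loop) - 1))
    v <- parallel_transport(m, g, loop[i], loop[i + 1], v)
  expect_equal(v, vec, tolerance = 1e-12)
  # curved surface: norm preserved and transport inverted by going back
  s <- fix_sphere(2)
  gs <- vertex_geometry(s)
  r2 <- one_ring(s, 30L)
  t0 <- gs$T1[30L, ] * 0.7
  fwd <- parallel_transport(s, gs, 30L, r2[1], t0)
  expect_equal(sqrt(sum(fwd^2)), sqrt(sum(t0^2)), tolerance = 1e-12)
  back <- parallel_transport(s, gs, r2[1], 30L, fwd)
  expect_equal(back, t0, tolerance = 1e-12)
})

test_that("transport around a spherical octant rotates by the enclosed solid angle", {
  # three vertices of a unit-sphere octant with exact radial normals; the
  # loop holonomy equals the octant solid angle pi/2
  V <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- list(vertices = V, box = dts_box(c(10, 10, 10)))
  geom <- list(normal = V) # radial normals
  vec <- c(0, 1, 0) # tangent at (1,0,0)
  loop <- c(1L, 2L, 3L, 1L)
  v <- vec
  for (i in 1:3) v <- parallel_transport(mesh, geom, loop[i], loop[i + 1], v)
  ang <- atan2(sum(c(1, 0, 0) * c(vec[2] * v[3] - vec[3] * v[2],
                                  vec[3] * v[1] - vec[1] * v[3],
                                  vec[1] * v[2] - vec[2] * v[1])),
               sum(v * vec))
  expect_equal(abs(ang), pi / 2, tolerance = 1e-9)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
})

test_that("pair angles: flat references and the gamma tip-to-tip sign rule", {
  m <- fix_flat(6)
  g <- vertex_geometry(m)
  v <- 15L
  w <- one_ring(m, v)[1]
  r <- drop(min_image(m$vertices[w, , drop = FALSE] - m$vertices[v, , drop = FALSE], m$box))
  rhat <- r / sqrt(sum(r^2))
  pa <- pair_angles(m, g, v, w, rhat, rhat)
  expect_equal(pa$Theta, 0, tolerance = 1e-12)
  expect_equal(pa$gamma, 0, tolerance = 1e-12)
  perp <- c(-rhat[2], rhat[1], 0)
  pa2 <- pair_angles(m, g, v, w, rhat, perp)
  expect_equal(abs(pa2$Theta), pi / 2, tolerance = 1e-12)
  # 4-vertex fold fixture: two triangles hinged on the transverse edge
  # (p, q); the wing vertices u, w carry their wing's face normal. Folding
  # the wings down (ridge) separates the normal tips -> gamma > 0; folding
  # them up (valley) brings the tips together -> gamma < 0.
  fold_geom <- function(h) {
    V <- rbind(c(-0.6, 0, h), c(0.6, 0, h), c(0, 0.8, 0), c(0, -0.8, 0))
    Tr <- rbind(c(3, 4, 2), c(4, 3, 1)) # wings share edge (3, 4)
    mesh <- dts_mesh(V, Tr, dts_box(c(20, 20, 20)))
    tg <- triangle_geometry(mesh)
    nrm <- rbind(tg$normal[2, ], tg$normal[1, ], tg$normal[1, ], tg$normal[2, ])
    list(mesh = mesh, geom = list(normal = nrm))
  }
  ridge <- fold_geom(-0.5) # wings fold down, normals tilt apart
  pr <- pair_angles(ridge$mesh, ridge$geom, 1L, 2L, c(0, 1, 0), c(0, 1, 0),
                    check_adjacent = FALSE)
  expect_gt(pr$gamma, 0)
  valley <- fold_geom(+0.5) # wings fold up, normal tips approach
  pv <- pair_angles(valley$mesh, valley$geom, 1L, 2L, c(0, 1, 0), c(0, 1, 0),
                    check_adjacent = FALSE)
  expect_lt(pv$gamma, 0)
  expect_equal(pr$gamma, -pv$gamma, tolerance = 1e-12)
})
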