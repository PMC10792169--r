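test_that("flat periodic grid has torus combinatorics and is exactly flat", {
  m <- build_flat_grid(4, 4, 1.2)
  ed <- mesh_edges(m)
  expect_equal(nrow(m$vertices), 16)
  expect_equal(nrow(m$triangles), 32)
  expect_equal(nrow(ed), 48)
  expect_equal(nrow(m$vertices) - nrow(ed) + nrow(m$triangles), 0) # chi = 0
  g <- vertex_geometry(m)
  expect_equal(max(abs(g$c1)), 0)
  expect_equal(max(abs(g$c2)), 0)
  expect_true(all(abs(g$normal[, 3] - 1) < 1e-12))
  expect_error(build_flat_grid(2, 4), "at least 3")
  expect_error(build_flat_grid(8, 8, spacing = 0.5), "window")
  expect_error(build_flat_grid(8, 8, spacing = 2), "window")
})

test_that("icosphere counts follow the subdivision recurrence and area converges", {
  m0 <- build_icosphere(0)
  e0 <- mesh_edges(m0)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$triangles), 20)
  expect_equal(nrow(e0), 30)
  # subdivision adds one vertex per edge: N_v(k+1) = N_v(k) + N_e(k),
  # N_T(k+1) = 4 N_T(k); iterate the recurrence as the oracle
  nv <- 12; ne <- 30; nt <- 20
  for (k in 1:2) {
    nv <- nv + ne
    nt <- 4 * nt
    ne <- nv + nt - 2 # Euler, chi = 2
  }
  m2 <- build_icosphere(2)
  expect_equal(nrow(m2$vertices), nv) # 162
  expect_equal(nrow(m2$triangles), nt)
  expect_equal(nrow(m2$vertices) - nrow(mesh_edges(m2)) + nrow(m2$triangles), 2)
  m3 <- fix_sphere(3)
  R <- sphere_radius(m3)
  g <- vertex_geometry(m3)
  expect_lt(abs(g$total_area / (4 * pi * R^2) - 1), 0.01)
  expect_equal(sum(g$area), g$total_area, tolerance = 1e-12)
})

test_that("tube is a periodic cylinder with the right counts and curvature", {
  m <- fix_tube()
  expect_equal(nrow(m$vertices), 144)
  ed <- mesh_edges(m)
  expect_equal(nrow(m$vertices) - nrow(ed) + nrow(m$triangles), 0)
  rho <- 1.25 / (2 * sin(pi / 12))
  g <- vertex_geometry(m)
  expect_true(all(abs(g$c1 * rho - 1) < 0.05))
  expect_true(all(abs(g$c2 * rho) < 0.05))
  # T1 circumferential: tangential direction is (-y, x, 0)/r
  tang <- cbind(-m$vertices[, 2], m$vertices[, 1], 0)
  tang <- tang / sqrt(rowSums(tang^2))
  cosang <- abs(rowSums(g$T1 * tang))
  expect_true(all(cosang > cos(5 * pi / 180)))
  expect_error(build_tube(12, 12, radius = 0.5), "window")
})

test_that("torus is a valid genus-1 surface obeying Gauss-Bonnet", {
  m <- fix_torus()
  rep <- validate_mesh(m)
  expect_true(rep$valid)
  expect_equal(rep$euler, 0)
  expect_equal(rep$genus, 1)
  g <- vertex_geometry(m)
  expect_lt(abs(sum(g$c1 * g$c2 * g$area)) / (4 * pi), 0.05)
  expect_error(build_torus(40, 8, 4, 5), "smaller")
})

test_that("validate_mesh reports manifold defects and genus", {
  s <- build_icosphere(1)
  rep <- validate_mesh(s)
  expect_true(rep$valid)
  expect_equal(rep$genus, 0)
  broken <- s
  broken$triangles <- broken$triangles[-1, , drop = FALSE]
  rep2 <- validate_mesh(broken)
  expect_false(rep2$valid)
  expect_true(any(grepl("boundary", rep2$defects)))
})

test_that("edge flip swaps the quad diagonal, conserves counts, and inverts", {
  m <- build_icosphere(1)
  ed <- mesh_edges(m)
  e <- 17
  a <- ed$v1[e]; b <- ed$v2[e]
  quad <- union(m$triangles[ed$t1[e], ], m$triangles[ed$t2[e], ])
  cd <- setdiff(quad, c(a, b))
  m2 <- flip_edge_topology(m, a, b)
  ed2 <- mesh_edges(m2)
  # counts conserved
  expect_equal(dim(m2$triangles), dim(m$triangles))
  expect_equal(nrow(ed2), nrow(ed))
  # old edge gone, new diagonal present
  expect_false(any(ed2$v1 == min(a, b) & ed2$v2 == max(a, b)))
  expect_true(any(ed2$v1 == min(cd) & ed2$v2 == max(cd)))
  # the two new triangles are (c,b,d) and (c,d,a) as vertex sets
  inc2 <- which(apply(m2$triangles, 1, function(r) all(cd %in% r)))
  sets <- lapply(inc2, function(t) sort(m2$triangles[t, ]))
  expect_true(any(vapply(sets, identical, TRUE, sort(c(cd, a)))))
  expect_true(any(vapply(sets, identical, TRUE, sort(c(cd, b)))))
  # still an orientable manifold
  expect_true(validate_mesh(m2)$valid)
  # involution: flipping the new edge restores the original connectivity
  m3 <- flip_edge_topology(m2, cd[1], cd[2])
  key <- function(mm) sort(apply(t(apply(mm$triangles, 1, sort)), 1, paste, collapse = "-"))
  expect_identical(key(m3), key(m))
})

test_that("illegal flips are refused", {
  m <- build_icosphere(1)
  ed <- mesh_edges(m)
  # flipping twice in the same quad region eventually hits the duplicate-edge
  # or degree guard; construct the duplicate case directly: flip an edge,
  # then try to flip a boundary edge of the same quad toward the new diagonal
  e <- 1
  a <- ed$v1[e]; b <- ed$v2[e]
  quad <- union(m$triangles[ed$t1[e], ], m$triangles[ed$t2[e], ])
  cd <- setdiff(quad, c(a, b))
  m2 <- flip_edge_topology(m, a, b)
  # now c and d are joined; flipping (a, c) within triangle (c,d,a)/(a,?,c)
  # would duplicate an edge or break degrees for some choice; at minimum,
  # re-flipping (a, b) must fail because the edge no longer exists
  expect_error(flip_edge_topology(m2, a, b), "not shared")
})
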