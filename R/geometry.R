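# Per-vertex discrete differential geometry.
#
# The estimator follows the edge-dihedral shape-operator construction used
# by dynamically-triangulated-surface models: each interior edge carries the
# integrated curvature tensor h_e (b x b) with h_e = 2 |e| sin(theta_e / 2)
# signed by convexity (theta_e the angle between the two face normals) and
# b the edge binormal; a vertex accumulates half of each incident edge's
# tensor, divides by its patch area A_v (one third of the incident triangle
# areas) and diagonalizes the tangent-plane projection, giving principal
# curvatures c1 >= c2 and directions T1, T2. Outward-normal spheres have
# c1, c2 > 0.

#' Per-vertex geometry of a mesh
#'
#' Computes patch areas, outward unit normals, principal curvatures
#' `c1 >= c2` and orthonormal principal directions for every vertex, via the
#' compiled shape-operator pass.
#'
#' @param mesh a [dts_mesh()].
#' @return An object of class `dts_geometry`: a list with vectors `area`,
#'   `c1`, `c2`, matrices `normal`, `T1`, `T2` (one row per vertex), the
#'   scalar `total_area`, and `volume` (enclosed volume, `NA` for periodic
#'   meshes). Mean curvature is `(c1 + c2) / 2`, Gaussian curvature
#'   `c1 * c2`.
#' @export
vertex_geometry <- function(mesh) {
  g <- cpp_geometry(mesh$vertices, mesh$triangles, mesh$box$L, mesh$box$periodic)
  class(g) <- "dts_geometry"
  g
}

#' @export
print.dts_geometry <- function(x, ...) {
  cat(sprintf("dts_geometry: %d vertices, total area %.4g, volume %s\n",
              length(x$area), x$total_area,
              if (is.na(x$volume)) "NA (periodic)" else sprintf("%.4g", x$volume)))
  invisible(x)
}

# R reference implementation of the same shape-operator scheme for a subset
# of vertices; independent of the compiled path, used for incremental
# refreshes and as a cross-check in the test suite.
r_vertex_geometry <- function(mesh, vids, geom) {
  V <- mesh$vertices; tr <- mesh$triangles; box <- mesh$box
  ed <- mesh_edges(mesh)
  tg <- triangle_geometry(mesh)
  vedges <- lapply(seq_len(nrow(V)), function(v) integer(0))
  for (e in seq_len(nrow(ed))) {
    vedges[[ed$v1[e]]] <- c(vedges[[ed$v1[e]]], e)
    vedges[[ed$v2[e]]] <- c(vedges[[ed$v2[e]]], e)
  }
  vtris <- lapply(seq_len(nrow(V)), function(v)
    which(tr[, 1] == v | tr[, 2] == v | tr[, 3] == v))
  for (v in vids) {
    ts <- vtris[[v]]
    A <- sum(tg$area[ts]) / 3
    n <- colSums(tg$area[ts] * tg$normal[ts, , drop = FALSE])
    n <- n / sqrt(sum(n^2))
    S <- matrix(0, 3, 3)
    for (e in vedges[[v]]) {
      t1 <- ed$t1[e]; t2 <- ed$t2[e]
      n1 <- tg$normal[t1, ]; n2 <- tg$normal[t2, ]
      evec <- drop(min_image(V[ed$v2[e], , drop = FALSE] -
                             V[ed$v1[e], , drop = FALSE], box))
      el <- sqrt(sum(evec^2))
      edir <- evec / el
      theta <- acos(max(-1, min(1, sum(n1 * n2))))
      c1c <- colMeans(min_image(V[tr[t1, ], , drop = FALSE] -
                                rep(V[ed$v1[e], ], each = 3), box))
      c2c <- colMeans(min_image(V[tr[t2, ], , drop = FALSE] -
                                rep(V[ed$v1[e], ], each = 3), box))
      s <- if (sum((n1 - n2) * (c1c - c2c)) >= 0) 1 else -1
      h <- 2 * el * sin(theta / 2) * s
      ne <- n1 + n2; ne <- ne / sqrt(sum(ne^2))
      b <- c(edir[2] * ne[3] - edir[3] * ne[2],
             edir[3] * ne[1] - edir[1] * ne[3],
             edir[1] * ne[2] - edir[2] * ne[1])
      nb <- sqrt(sum(b^2))
      if (nb < 1e-14) next
      b <- b / nb
      S <- S + h * (b %o% b)
    }
    S <- S / (2 * A)
    t1r <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1r <- t1r - sum(t1r * n) * n
    t1r <- t1r / sqrt(sum(t1r^2))
    t2r <- c(n[2] * t1r[3] - n[3] * t1r[2],
             n[3] * t1r[1] - n[1] * t1r[3],
             n[1] * t1r[2] - n[2] * t1r[1])
    a11 <- drop(t1r %*% S %*% t1r)
    a12 <- drop(t1r %*% S %*% t2r)
    a22 <- drop(t2r %*% S %*% t2r)
    tr2 <- a11 + a22
    disc <- sqrt(0.25 * (a11 - a22)^2 + a12^2)
    c1 <- tr2 / 2 + disc; c2 <- tr2 / 2 - disc
    if (c1 - c2 < 1e-9) {
      T1 <- t1r
    } else {
      e1 <- c(a12, c1 - a11)
      if (sum(abs(e1)) < 1e-14) e1 <- c(c1 - a22, a12)
      e1 <- e1 / sqrt(sum(e1^2))
      T1 <- e1[1] * t1r + e1[2] * t2r
    }
    T2 <- c(n[2] * T1[3] - n[3] * T1[2],
            n[3] * T1[1] - n[1] * T1[3],
            n[1] * T1[2] - n[2] * T1[1])
    geom$area[v] <- A; geom$normal[v, ] <- n
    geom$c1[v] <- c1; geom$c2[v] <- c2
    geom$T1[v, ] <- T1; geom$T2[v, ] <- T2
  }
  geom
}

#' Refresh the geometry of the region affected by moved vertices
#'
#' After moving a set of vertices, exactly the moved vertices and their
#' one-ring neighbours have stale `dts_geometry` entries (a vertex's shape
#' operator depends only on its incident triangles). This recomputes that
#' dependency region in place and returns the updated geometry with the
#' refreshed vertex set attached.
#'
#' @param mesh the mesh after the move.
#' @param geom the (partially stale) [vertex_geometry()] result.
#' @param moved integer vector of moved vertex indices (may be empty).
#' @return The updated geometry, with attribute `refreshed` listing the
#'   recomputed vertices.
#' @export
refresh_region <- function(mesh, geom, moved) {
  moved <- unique(as.integer(moved))
  if (length(moved) == 0) {
    attr(geom, "refreshed") <- integer(0)
    return(geom)
  }
  region <- moved
  for (v in moved) region <- c(region, one_ring(mesh, v))
  region <- sort(unique(region))
  geom <- r_vertex_geometry(mesh, region, geom)
  tg <- triangle_geometry(mesh)
  geom$total_area <- sum(tg$area)
  if (!any(mesh$box$periodic)) geom$volume <- sum(tg$volume)
  attr(geom, "refreshed") <- region
  geom
}

#' Directional curvatures from Euler's curvature formula
#'
#' Curvature of the surface along a direction at angle `theta` from the
#' first principal direction, and along the perpendicular direction:
#' `C_par = c1 cos^2(theta) + c2 sin^2(theta)`,
#' `C_perp = c1 sin^2(theta) + c2 cos^2(theta)`. Their sum is the trace
#' invariant `c1 + c2` for any `theta`.
#'
#' @param c1,c2 principal curvatures.
#' @param theta angle (radians) from the first principal direction.
#' @return A list with numeric `C_par` and `C_perp` (vectorized).
#' @export
euler_directional_curvatures <- function(c1, c2, theta) {
  ct2 <- cos(theta)^2
  st2 <- sin(theta)^2
  list(C_par = c1 * ct2 + c2 * st2, C_perp = c1 * st2 + c2 * ct2)
}

#' Parallel transport of a tangent vector between adjacent vertices
#'
#' The connecting edge is projected into the tangent plane of each vertex;
#' the transported vector keeps the signed angle it makes with that
#' projection (and its norm). This is the transport rule under which an
#' inclusion's orientation is carried along when it hops between vertices.
#'
#' @param mesh a [dts_mesh()].
#' @param geom its [vertex_geometry()].
#' @param v_from,v_to adjacent vertex indices.
#' @param vec tangent 3-vector at `v_from`.
#' @return The transported tangent 3-vector at `v_to`.
#' @export
parallel_transport <- function(mesh, geom, v_from, v_to, vec) {
  r <- drop(min_image(mesh$vertices[v_to, , drop = FALSE] -
                      mesh$vertices[v_from, , drop = FALSE], mesh$box))
  nu <- geom$normal[v_from, ]; nw <- geom$normal[v_to, ]
  a <- r - sum(r * nu) * nu
  b <- r - sum(r * nw) * nw
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12)
    stop("edge projection vanishes (edge parallel to a vertex normal)")
  a <- a / na; b <- b / nb
  aperp <- c(nu[2] * a[3] - nu[3] * a[2], nu[3] * a[1] - nu[1] * a[3],
             nu[1] * a[2] - nu[2] * a[1])
  bperp <- c(nw[2] * b[3] - nw[3] * b[2], nw[3] * b[1] - nw[1] * b[3],
             nw[1] * b[2] - nw[2] * b[1])
  sum(vec * a) * b + sum(vec * aperp) * bperp
}

#' Relative in-plane angle and normal angle of two neighbouring inclusions
#'
#' For inclusions on adjacent vertices `v_i`, `v_j` with in-plane
#' orientations `dir_i`, `dir_j`: each orientation's signed angle
#' `Theta_k` is measured from the tangent-plane projection of the line
#' connecting the two vertices; `Theta = Theta_j - Theta_i`. `gamma` is the
#' angle between the two vertex normals, positive if the tip-to-tip
#' distance of the normals (each placed at its vertex) exceeds the edge
#' length (ridge) and negative otherwise (valley).
#'
#' @param mesh a [dts_mesh()].
#' @param geom its [vertex_geometry()].
#' @param v_i,v_j adjacent host vertex indices.
#' @param dir_i,dir_j unit tangent orientation vectors at the two hosts.
#' @param check_adjacent verify that the hosts share an edge (the
#'   interaction range of the pair potential); disable only for geometric
#'   fixtures.
#' @return A list with `Theta`, `gamma`, and the per-vertex angles
#'   `Theta_i`, `Theta_j`.
#' @export
pair_angles <- function(mesh, geom, v_i, v_j, dir_i, dir_j,
                        check_adjacent = TRUE) {
  if (check_adjacent) {
    tr <- mesh$triangles
    shared <- sum((tr[, 1] == v_i | tr[, 2] == v_i | tr[, 3] == v_i) &
                  (tr[, 1] == v_j | tr[, 2] == v_j | tr[, 3] == v_j))
    if (shared == 0) stop("host vertices are not adjacent")
  }
  r <- drop(min_image(mesh$vertices[v_j, , drop = FALSE] -
                      mesh$vertices[v_i, , drop = FALSE], mesh$box))
  ni <- geom$normal[v_i, ]; nj <- geom$normal[v_j, ]
  signed_angle <- function(n, ref, d) {
    p <- ref - sum(ref * n) * n
    np <- sqrt(sum(p^2))
    if (np < 1e-12) stop("edge projection vanishes")
    p <- p / np
    cr <- c(p[2] * d[3] - p[3] * d[2], p[3] * d[1] - p[1] * d[3],
            p[1] * d[2] - p[2] * d[1])
    atan2(sum(n * cr), sum(p * d))
  }
  Ti <- signed_angle(ni, r, dir_i)
  Tj <- signed_angle(nj, r, dir_j)
  g <- acos(max(-1, min(1, sum(ni * nj))))
  tip <- r + nj - ni
  if (sum(tip^2) < sum(r^2)) g <- -g
  list(Theta = Tj - Ti, gamma = g, Theta_i = Ti, Theta_j = Tj)
}
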