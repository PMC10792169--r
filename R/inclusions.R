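# Protein inclusions: vertex-bound, in-plane oriented, at most one per
# vertex (which is what gives the model its in-plane excluded volume).

#' Inclusion (protein) type
#'
#' Type-1 inclusions couple isotropically to curvature (suitable for
#' proteins with rotationally symmetric membrane interactions, e.g. the B
#' subunits of cholera and Shiga toxin); their site energy is
#' `(2 dkappa H^2 - 2 (dkappa + kappa) c0 H - dkappa_G K) * A_v`.
#' Type-2 inclusions break in-plane symmetry (BAR domains, dynamin);
#' their site energy is
#' `(k1/2 (C_par - C_par0)^2 + k2/2 (C_perp - C_perp0)^2) * A_v` with the
#' directional curvatures from [euler_directional_curvatures()].
#'
#' @param name type name (used in files and pair-potential lookups).
#' @param class `"type1"` or `"type2"`.
#' @param dkappa,dkappa_G,c0 type-1 parameters: added bending rigidity and
#'   Gaussian modulus (kBT) and imprinted local curvature (1 / length).
#' @param k1,k2 type-2 directional rigidities (kBT, non-negative).
#' @param C_par0,C_perp0 preferred curvatures along / perpendicular to the
#'   inclusion orientation (1 / length).
#' @return An object of class `inclusion_type`.
#' @export
inclusion_type <- function(name, class = c("type1", "type2"),
                           dkappa = 0, dkappa_G = 0, c0 = 0,
                           k1 = 0, k2 = 0, C_par0 = 0, C_perp0 = 0) {
  class <- match.arg(class)
  if (k1 < 0 || k2 < 0) stop("k1 and k2 must be non-negative")
  structure(list(name = name, class = class,
                 dkappa = dkappa, dkappa_G = dkappa_G, c0 = c0,
                 k1 = k1, k2 = k2, C_par0 = C_par0, C_perp0 = C_perp0),
            class = "inclusion_type")
}

#' Pair interaction potential between two inclusion types
#'
#' Lowest-order Fourier interaction of two inclusions on edge-adjacent
#' vertices: `e = -A - B cos(n (Theta - Theta_0)) - C cos(gamma - gamma_0)`
#' with `Theta` and `gamma` from [pair_angles()]. `n` is the least common
#' multiple of the two types' in-plane symmetry degrees.
#'
#' @param type_i,type_j names of the two types (order irrelevant).
#' @param A,B,C strength coefficients (kBT).
#' @param n in-plane symmetry order (integer >= 1).
#' @param Theta0 phase shift (radians).
#' @param gamma0 preferred normal-angle (radians); nonzero values let an
#'   adjacent pair imprint membrane curvature.
#' @return An object of class `pair_potential`.
#' @export
pair_potential <- function(type_i, type_j, A = 0, B = 0, C = 0, n = 1,
                           Theta0 = 0, gamma0 = 0) {
  if (n < 1) stop("symmetry order n must be >= 1")
  structure(list(type_i = type_i, type_j = type_j, A = A, B = B, C = C,
                 n = as.integer(n), Theta0 = Theta0, gamma0 = gamma0),
            class = "pair_potential")
}

#' Inclusion field on a mesh
#'
#' @param vertex integer vector of host vertices (no duplicates: at most one
#'   inclusion per vertex).
#' @param type integer vector (same length) of indices into `types`.
#' @param dir matrix of in-plane unit orientation vectors, one row per
#'   inclusion, or `NULL` to initialize along each host's first principal
#'   direction.
#' @param types list of [inclusion_type()] objects.
#' @param pair_potentials list of [pair_potential()] objects.
#' @return An object of class `dts_inclusions`.
#' @export
dts_inclusions <- function(vertex, type, dir = NULL, types,
                           pair_potentials = list()) {
  vertex <- as.integer(vertex)
  type <- as.integer(type)
  if (anyDuplicated(vertex) > 0) stop("at most one inclusion per vertex")
  stopifnot(length(vertex) == length(type))
  if (!is.null(dir)) {
    dir <- as.matrix(dir)
    stopifnot(nrow(dir) == length(vertex), ncol(dir) == 3)
  }
  structure(list(vertex = vertex, type = type, dir = dir, types = types,
                 pair_potentials = pair_potentials),
            class = "dts_inclusions")
}

#' Randomly place inclusions at a coverage fraction
#'
#' Hosts are drawn by seeded uniform sampling of unoccupied vertices; the
#' inclusion count is `round(coverage * N_v)`. Orientations start along
#' each host's first principal direction.
#'
#' @param mesh a [dts_mesh()].
#' @param types list of [inclusion_type()] objects.
#' @param coverage fraction of vertices to occupy, in `[0, 1]`; may be a
#'   vector with one entry per type.
#' @param pair_potentials list of [pair_potential()] objects.
#' @return A [dts_inclusions()].
#' @export
place_inclusions <- function(mesh, types, coverage,
                             pair_potentials = list()) {
  nv <- nrow(mesh$vertices)
  if (length(coverage) == 1 && length(types) > 1)
    coverage <- rep(coverage / length(types), length(types))
  if (any(coverage < 0) || sum(coverage) > 1)
    stop("coverage must be within [0, 1]")
  counts <- round(coverage * nv)
  hosts <- sample.int(nv, sum(counts))
  geom <- vertex_geometry(mesh)
  dts_inclusions(vertex = hosts,
                 type = rep(seq_along(counts), counts),
                 dir = geom$T1[hosts, , drop = FALSE],
                 types = types, pair_potentials = pair_potentials)
}

#' Site energy of a type-1 (isotropic) inclusion
#'
#' @param H,K,A_v mean curvature, Gaussian curvature, and patch area of the
#'   host vertex (vectorized).
#' @param params an [inclusion_type()] of class `"type1"`.
#' @param kappa the membrane bending rigidity (kBT), read from the membrane
#'   parameters so it has a single source of truth.
#' @return Energy in kBT.
#' @export
type1_site_energy <- function(H, K, A_v, params, kappa) {
  (2 * params$dkappa * H^2 - 2 * (params$dkappa + kappa) * params$c0 * H -
     params$dkappa_G * K) * A_v
}

#' Site energy of a type-2 (anisotropic) inclusion
#'
#' The inclusion's angle `theta` from the first principal direction sets the
#' directional curvatures via Euler's formula; the energy is harmonic in
#' their deviations from the preferred values. Invariant under
#' `dir -> -dir` (nematic symmetry).
#'
#' @param geom a [vertex_geometry()].
#' @param v host vertex index.
#' @param dir in-plane unit orientation vector at the host.
#' @param params an [inclusion_type()] of class `"type2"`.
#' @return Energy in kBT.
#' @export
type2_site_energy <- function(geom, v, dir, params) {
  ct <- sum(dir * geom$T1[v, ])
  st <- sum(dir * geom$T2[v, ])
  n2 <- ct^2 + st^2
  if (n2 < 1e-14) n2 <- 1
  cpar <- (geom$c1[v] * ct^2 + geom$c2[v] * st^2) / n2
  cperp <- (geom$c1[v] * st^2 + geom$c2[v] * ct^2) / n2
  (params$k1 / 2 * (cpar - params$C_par0)^2 +
     params$k2 / 2 * (cperp - params$C_perp0)^2) * geom$area[v]
}

#' Pair interaction energy
#'
#' @param Theta relative in-plane angle (radians).
#' @param gamma signed normal angle (radians).
#' @param pot a [pair_potential()].
#' @return Energy in kBT:
#'   `-A - B cos(n (Theta - Theta_0)) - C cos(gamma - gamma_0)`.
#' @export
pair_energy <- function(Theta, gamma, pot) {
  -pot$A - pot$B * cos(pot$n * (Theta - pot$Theta0)) -
    pot$C * cos(gamma - pot$gamma0)
}

# potential lookup by the two type names; NULL when no interaction defined
find_pair_potential <- function(incl, name_i, name_j) {
  for (p in incl$pair_potentials) {
    if ((p$type_i == name_i && p$type_j == name_j) ||
        (p$type_i == name_j && p$type_j == name_i)) return(p)
  }
  NULL
}

#' Total inclusion field energy
#'
#' Sum of site energies over occupied vertices plus pair energies over
#' unique edge-adjacent occupied pairs (nearest-neighbour interaction range
#' of one edge; each pair counted once).
#'
#' @param state a [simulation_state()] (or a list with `mesh`, `membrane`,
#'   `inclusions`).
#' @param geom optional precomputed [vertex_geometry()].
#' @return Energy in kBT.
#' @export
inclusion_field_energy <- function(state, geom = NULL) {
  incl <- state$inclusions
  if (is.null(incl) || length(incl$vertex) == 0) return(0)
  mesh <- state$mesh
  if (is.null(geom)) geom <- vertex_geometry(mesh)
  kappa <- state$membrane$kappa
  e <- 0
  occ <- rep(NA_integer_, nrow(mesh$vertices))
  occ[incl$vertex] <- seq_along(incl$vertex)
  for (i in seq_along(incl$vertex)) {
    v <- incl$vertex[i]
    ty <- incl$types[[incl$type[i]]]
    if (ty$class == "type1") {
      H <- (geom$c1[v] + geom$c2[v]) / 2
      e <- e + type1_site_energy(H, geom$c1[v] * geom$c2[v], geom$area[v], ty, kappa)
    } else {
      e <- e + type2_site_energy(geom, v, incl$dir[i, ], ty)
    }
  }
  ed <- mesh_edges(mesh)
  both <- !is.na(occ[ed$v1]) & !is.na(occ[ed$v2])
  for (k in which(both)) {
    i <- occ[ed$v1[k]]; j <- occ[ed$v2[k]]
    ty_i <- incl$types[[incl$type[i]]]$name
    ty_j <- incl$types[[incl$type[j]]]$name
    pot <- find_pair_potential(incl, ty_i, ty_j)
    if (is.null(pot)) next
    ang <- pair_angles(mesh, geom, ed$v1[k], ed$v2[k],
                       incl$dir[i, ], incl$dir[j, ])
    e <- e + pair_energy(ang$Theta, ang$gamma, pot)
  }
  e
}
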