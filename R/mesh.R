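#' Simulation box
#'
#' A rectangular box with per-axis periodicity. Framed (flat) membranes are
#' periodic in x and y; closed surfaces (vesicles, tori) use a non-periodic
#' box whose dimensions are irrelevant to the energetics.
#'
#' @param L numeric length-3 vector of box edge lengths (DTS length units).
#' @param periodic logical length-3 vector of periodic flags per axis.
#' @return An object of class `dts_box`.
#' @export
dts_box <- function(L, periodic = c(FALSE, FALSE, FALSE)) {
  L <- as.numeric(L)
  stopifnot(length(L) == 3, length(periodic) == 3)
  if (any(L <= 0)) stop("box lengths must be positive")
  structure(list(L = L, periodic = as.logical(periodic)), class = "dts_box")
}

#' Triangulated surface mesh
#'
#' The central data structure: vertex positions, triangles in consistent
#' winding (counter-clockwise seen from the outward normal), and a box.
#' Positions are kept unwrapped; all distance and area computations use
#' minimum-image displacements on periodic axes.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z).
#' @param triangles integer matrix, one row per triangle (three 1-based
#'   vertex indices).
#' @param box a [dts_box()].
#' @param domain optional integer vector of per-vertex domain labels.
#' @return An object of class `dts_mesh`.
#' @export
dts_mesh <- function(vertices, triangles, box, domain = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (min(triangles) < 1 || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  if (is.null(domain)) domain <- integer(nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles, box = box,
                 domain = as.integer(domain)),
            class = "dts_mesh")
}

#' @export
print.dts_mesh <- function(x, ...) {
  e <- mesh_edges(x)
  cat(sprintf("dts_mesh: %d vertices, %d edges, %d triangles\n",
              nrow(x$vertices), nrow(e), nrow(x$triangles)))
  chi <- nrow(x$vertices) - nrow(e) + nrow(x$triangles)
  cat(sprintf("  Euler characteristic %d; box [%.3g %.3g %.3g] periodic [%s]\n",
              chi, x$box$L[1], x$box$L[2], x$box$L[3],
              paste(ifelse(x$box$periodic, "T", "F"), collapse = " ")))
  invisible(x)
}

# minimum-image displacement rows of `d` under the box
min_image <- function(d, box) {
  for (k in which(box$periodic)) d[, k] <- d[, k] - box$L[k] * round(d[, k] / box$L[k])
  d
}

#' Edge table of a mesh
#'
#' Each undirected edge is listed once with canonical (min, max) vertex key
#' and its one or two incident triangles.
#'
#' @param mesh a [dts_mesh()].
#' @return A data.frame with columns `v1`, `v2`, `t1`, `t2` (NA for a
#'   boundary edge) and `length`.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  a <- c(tr[, 1], tr[, 2], tr[, 3])
  b <- c(tr[, 2], tr[, 3], tr[, 1])
  tid <- rep(seq_len(nrow(tr)), 3)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  n <- sum(first)
  t1 <- rep(NA_integer_, n); t2 <- rep(NA_integer_, n)
  for (i in seq_along(key)) {
    j <- idx[i]
    if (is.na(t1[j])) t1[j] <- tid[i]
    else if (is.na(t2[j])) t2[j] <- tid[i]
    else stop("edge shared by more than two triangles")
  }
  v1 <- lo[first]; v2 <- hi[first]
  d <- min_image(mesh$vertices[v2, , drop = FALSE] -
                 mesh$vertices[v1, , drop = FALSE], mesh$box)
  data.frame(v1 = v1, v2 = v2, t1 = t1, t2 = t2, length = sqrt(rowSums(d^2)))
}

# ordered one-ring of vertex v (counter-clockwise seen from the outward
# normal); NULL if the ring is not a single closed cycle
one_ring <- function(mesh, v) {
  tr <- mesh$triangles
  inc <- which(tr[, 1] == v | tr[, 2] == v | tr[, 3] == v)
  if (length(inc) < 3) return(NULL)
  nxt <- rep(NA_integer_, nrow(mesh$vertices))
  for (t in inc) {
    r <- tr[t, ]
    i <- which(r == v)
    # triangle (v, a, b): around v the winding takes a -> b
    a <- r[i %% 3 + 1]; b <- r[(i + 1) %% 3 + 1]
    if (!is.na(nxt[a])) return(NULL)
    nxt[a] <- b
  }
  start <- tr[inc[1], ][which(tr[inc[1], ] == v) %% 3 + 1]
  ring <- integer(length(inc))
  cur <- start
  for (i in seq_along(ring)) {
    ring[i] <- cur
    cur <- nxt[cur]
    if (is.na(cur)) return(NULL)
  }
  if (cur != start || anyDuplicated(ring) > 0) return(NULL)
  ring
}

#' Validate mesh topology and constraints
#'
#' Reports whether the mesh is a closed orientable manifold (every edge
#' shared by exactly two triangles, consistent winding, single-cycle
#' one-rings), its Euler characteristic and genus, and any edge-length or
#' dihedral violations under the given constraint set.
#'
#' @param mesh a [dts_mesh()].
#' @param constraints a [dts_constraints()] used for the edge-window and
#'   dihedral audit.
#' @return A list with elements `valid`, `euler`, `genus`, `defects`
#'   (character vector), `n_edge_violations`, `n_dihedral_violations`.
#' @export
validate_mesh <- function(mesh, constraints = dts_constraints()) {
  defects <- character(0)
  tr <- mesh$triangles
  nv <- nrow(mesh$vertices); nt <- nrow(tr)
  ed <- tryCatch(mesh_edges(mesh), error = function(e) conditionMessage(e))
  if (is.character(ed)) {
    return(list(valid = FALSE, euler = NA, genus = NA, defects = ed,
                n_edge_violations = NA, n_dihedral_violations = NA))
  }
  ne <- nrow(ed)
  nb <- sum(is.na(ed$t2))
  if (nb > 0) defects <- c(defects, sprintf("%d boundary edge(s)", nb))
  # consistent orientation: each directed edge appears exactly once
  a <- c(tr[, 1], tr[, 2], tr[, 3]); b <- c(tr[, 2], tr[, 3], tr[, 1])
  if (anyDuplicated(paste(a, b)) > 0)
    defects <- c(defects, "inconsistent triangle winding")
  bad_ring <- 0L
  for (v in seq_len(nv)) if (is.null(one_ring(mesh, v))) bad_ring <- bad_ring + 1L
  if (bad_ring > 0)
    defects <- c(defects, sprintf("%d vertex one-ring(s) not a single closed cycle", bad_ring))
  chi <- nv - ne + nt
  genus <- if (chi %% 2 == 0) (2 - chi) %/% 2 else NA_integer_
  nev <- sum(ed$length < constraints$l_min - 1e-12 |
             ed$length > constraints$l_max + 1e-12)
  ndi <- 0L
  if (nb == 0) {
    g <- triangle_geometry(mesh)
    cosd <- rowSums(g$normal[ed$t1, , drop = FALSE] * g$normal[ed$t2, , drop = FALSE])
    ndi <- sum(cosd < constraints$min_dihedral_cos - 1e-12)
  }
  list(valid = length(defects) == 0, euler = chi, genus = genus,
       defects = defects, n_edge_violations = nev, n_dihedral_violations = ndi)
}

# per-triangle areas, unit normals and signed origin-tetrahedron volumes
triangle_geometry <- function(mesh) {
  V <- mesh$vertices; tr <- mesh$triangles
  u <- min_image(V[tr[, 2], , drop = FALSE] - V[tr[, 1], , drop = FALSE], mesh$box)
  w <- min_image(V[tr[, 3], , drop = FALSE] - V[tr[, 1], , drop = FALSE], mesh$box)
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  a2 <- sqrt(rowSums(cr^2))
  p1 <- V[tr[, 1], , drop = FALSE]; p2 <- V[tr[, 2], , drop = FALSE]
  p3 <- V[tr[, 3], , drop = FALSE]
  vol <- (p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
          p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  list(area = a2 / 2, normal = cr / a2, volume = vol)
}

#' Flip the shared edge of two adjacent triangles
#'
#' The topological half of the Alexander (link-flip) move: the diagonal of
#' the quadrilateral formed by the two triangles incident to edge
#' `(a, b)` is replaced by the opposite diagonal. Counts of vertices, edges
#' and triangles are conserved. The flip is performed regardless of edge
#' length: rejecting geometrically illegal flips is the sampler's job.
#'
#' @param mesh a [dts_mesh()].
#' @param a,b vertex indices of the edge to flip.
#' @return The mesh with rewired connectivity.
#' @export
flip_edge_topology <- function(mesh, a, b) {
  tr <- mesh$triangles
  has <- function(t, v) any(tr[t, ] == v)
  inc <- which((tr[, 1] == a | tr[, 2] == a | tr[, 3] == a) &
               (tr[, 1] == b | tr[, 2] == b | tr[, 3] == b))
  if (length(inc) != 2) stop("edge not shared by exactly two triangles")
  t1 <- inc[1]; t2 <- inc[2]
  # orient so t1 holds the directed edge a -> b
  dir1 <- any(tr[t1, ] == a & tr[t1, c(2, 3, 1)] == b)
  if (!dir1) { tmp <- a; a <- b; b <- tmp }
  cc <- setdiff(tr[t1, ], c(a, b))
  dd <- setdiff(tr[t2, ], c(a, b))
  if (length(cc) != 1 || length(dd) != 1) stop("degenerate quad")
  ed <- mesh_edges(mesh)
  if (any((ed$v1 == min(cc, dd)) & (ed$v2 == max(cc, dd))))
    stop("flip would duplicate an existing edge")
  dega <- sum(ed$v1 == a | ed$v2 == a)
  degb <- sum(ed$v1 == b | ed$v2 == b)
  if (dega <= 3 || degb <= 3)
    stop("flip would leave a vertex with fewer than 3 neighbors")
  mesh$triangles[t1, ] <- c(b, cc, dd)
  mesh$triangles[t2, ] <- c(a, dd, cc)
  mesh
}
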