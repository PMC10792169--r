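# Mesh generators: flat periodic sheet, icosphere, tube, torus.
# All generators emit consistently wound meshes with outward (or +z) normals
# and check the self-avoidance edge window on their output.

check_edge_window <- function(mesh, l_min, l_max, what) {
  ed <- mesh_edges(mesh)
  if (any(ed$length < l_min - 1e-9) || any(ed$length > l_max + 1e-9))
    stop(sprintf("%s: edge lengths [%.3f, %.3f] violate the window [%.3f, %.3f]",
                 what, min(ed$length), max(ed$length), l_min, l_max))
  invisible(mesh)
}

# triangle table of an (nx x ny)-vertex triangular lattice with odd rows
# offset by half a spacing; both directions close periodically (ny even)
lattice_triangles <- function(nx, ny) {
  idx <- function(i, j) (j %% ny) * nx + (i %% nx) + 1L
  tr <- matrix(0L, 2L * nx * ny, 3L)
  r <- 1L
  for (j in 0:(ny - 1L)) {
    o <- j %% 2L   # offset of row j
    for (i in 0:(nx - 1L)) {
      if (o == 0L) {
        tr[r, ] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
        tr[r + 1L, ] <- c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      } else {
        tr[r, ] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
        tr[r + 1L, ] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      }
      r <- r + 2L
    }
  }
  tr
}

#' Flat periodic membrane sheet
#'
#' An equilateral triangular lattice closed through periodic boundaries in x
#' and y (torus topology, Euler characteristic 0), the standard starting
#' configuration for framed-membrane simulations at fixed or zero frame
#' tension.
#'
#' @param nx,ny number of vertices along x and y; both at least 3 and `ny`
#'   even (offset rows must close periodically).
#' @param spacing lattice spacing (DTS length units); must lie inside the
#'   edge window.
#' @param Lz box height for the non-periodic z axis.
#' @param l_min,l_max edge window used to sanity-check the output.
#' @return A [dts_mesh()] with `2*nx*ny` triangles.
#' @export
build_flat_grid <- function(nx, ny, spacing = 1.25, Lz = 60,
                            l_min = 1, l_max = sqrt(3)) {
  if (nx < 3 || ny < 3) stop("nx and ny must be at least 3")
  if (ny %% 2 != 0) stop("ny must be even for periodic closure of offset rows")
  if (spacing < l_min || spacing > l_max)
    stop("spacing outside the edge window")
  rowh <- spacing * sqrt(3) / 2
  j <- rep(0:(ny - 1L), each = nx)
  i <- rep(0:(nx - 1L), ny)
  V <- cbind((i + 0.5 * (j %% 2)) * spacing, j * rowh, 0)
  box <- dts_box(c(nx * spacing, ny * rowh, Lz), periodic = c(TRUE, TRUE, FALSE))
  mesh <- dts_mesh(V, lattice_triangles(nx, ny), box)
  check_edge_window(mesh, l_min, l_max, "build_flat_grid")
}

# unit icosahedron subdivided k times, vertices projected to the unit sphere
icosphere_unit <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  Tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(V)
    key <- new.env(hash = TRUE)
    Vl <- V
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      m <- get0(k, envir = key)
      if (!is.null(m)) return(m)
      p <- Vl[a, ] + Vl[b, ]
      Vl <<- rbind(Vl, p / sqrt(sum(p^2)))
      assign(k, nrow(Vl), envir = key)
      nrow(Vl)
    }
    T2 <- matrix(0L, nrow(Tr) * 4L, 3L)
    r <- 1L
    for (t in seq_len(nrow(Tr))) {
      a <- Tr[t, 1]; b <- Tr[t, 2]; cc <- Tr[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      T2[r, ] <- c(a, ab, ca); T2[r + 1L, ] <- c(b, bc, ab)
      T2[r + 2L, ] <- c(cc, ca, bc); T2[r + 3L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    V <- Vl; Tr <- T2
  }
  list(vertices = V, triangles = Tr)
}

#' Icosphere (subdivided icosahedron) vesicle mesh
#'
#' Closed genus-0 mesh with outward normals; the standard vesicle fixture.
#' If `radius` is omitted it is chosen so the shortest edge sits just above
#' the hard-core length `l_min`.
#'
#' @param subdivisions number of 4-to-1 subdivision passes (>= 0).
#' @param radius sphere radius; `NULL` for automatic sizing.
#' @param l_min,l_max edge window the output must satisfy.
#' @return A [dts_mesh()].
#' @export
build_icosphere <- function(subdivisions, radius = NULL,
                            l_min = 1, l_max = sqrt(3)) {
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  ico <- icosphere_unit(subdivisions)
  d <- ico$vertices[ico$triangles[, 1], ] - ico$vertices[ico$triangles[, 2], ]
  emin <- sqrt(min(rowSums(d^2)))
  if (is.null(radius)) radius <- 1.05 * l_min / emin
  V <- ico$vertices * radius
  ext <- 4 * radius
  mesh <- dts_mesh(V, ico$triangles, dts_box(c(ext, ext, ext)))
  check_edge_window(mesh, l_min, l_max, "build_icosphere")
}

#' Cylindrical membrane tube, periodic along its axis
#'
#' A triangular lattice wrapped into a cylinder of the given radius,
#' periodic along z (Euler characteristic 0). Normals point radially
#' outward.
#'
#' @param n_axial number of vertex rings along the axis (even).
#' @param n_circ number of vertices per ring.
#' @param radius cylinder radius.
#' @param length axial box length (periodic); defaults to
#'   `n_axial * sqrt(3)/2 * (2 * radius * sin(pi / n_circ))` which makes the
#'   lattice near-equilateral.
#' @param l_min,l_max edge window the output must satisfy.
#' @return A [dts_mesh()].
#' @export
build_tube <- function(n_axial, n_circ, radius, length = NULL,
                       l_min = 1, l_max = sqrt(3)) {
  if (n_axial < 3 || n_circ < 3) stop("n_axial and n_circ must be at least 3")
  if (n_axial %% 2 != 0) stop("n_axial must be even for periodic closure")
  chord <- 2 * radius * sin(pi / n_circ)
  if (is.null(length)) length <- n_axial * sqrt(3) / 2 * chord
  dz <- length / n_axial
  j <- rep(0:(n_axial - 1L), each = n_circ)
  i <- rep(0:(n_circ - 1L), n_axial)
  ang <- 2 * pi * (i + 0.5 * (j %% 2)) / n_circ
  V <- cbind(radius * cos(ang), radius * sin(ang), j * dz)
  ext <- 4 * radius
  box <- dts_box(c(ext, ext, length), periodic = c(FALSE, FALSE, TRUE))
  mesh <- dts_mesh(V, lattice_triangles(n_circ, n_axial), box)
  check_edge_window(mesh, l_min, l_max, "build_tube")
}

#' Torus mesh (genus 1)
#'
#' Closed genus-1 fixture with outward normals, triangulated on an offset
#' lattice over the (major, minor) angle grid.
#'
#' @param n_major,n_minor vertices around the major and minor circles
#'   (`n_minor` even).
#' @param R_major,r_minor major and minor radii (`r_minor < R_major`).
#' @param l_min,l_max edge window the output must satisfy.
#' @return A [dts_mesh()].
#' @export
build_torus <- function(n_major, n_minor, R_major, r_minor,
                        l_min = 1, l_max = sqrt(3)) {
  if (r_minor >= R_major) stop("r_minor must be smaller than R_major")
  if (n_major < 3 || n_minor < 3) stop("need at least 3 vertices per circle")
  if (n_minor %% 2 != 0) stop("n_minor must be even for periodic closure")
  j <- rep(0:(n_minor - 1L), each = n_major)
  i <- rep(0:(n_major - 1L), n_minor)
  th <- 2 * pi * (i + 0.5 * (j %% 2)) / n_major
  ph <- 2 * pi * j / n_minor
  V <- cbind((R_major + r_minor * cos(ph)) * cos(th),
             (R_major + r_minor * cos(ph)) * sin(th),
             r_minor * sin(ph))
  ext <- 4 * (R_major + r_minor)
  mesh <- dts_mesh(V, lattice_triangles(n_major, n_minor), dts_box(c(ext, ext, ext)))
  check_edge_window(mesh, l_min, l_max, "build_torus")
}
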