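# File formats and configuration.
#
# The native frame format is line-oriented ASCII with a versioned header,
# 0-based indices and full-precision (%.17g) numbers so that
# write -> read -> write round-trips bit-exactly:
#
#   dtsframe 1
#   box <Lx> <Ly> <Lz> <px> <py> <pz>
#   vertices <N>
#   <id> <x> <y> <z> <domain>
#   triangles <NT>
#   <id> <v1> <v2> <v3>
#   inclusions <NI>
#   <id> <type-name> <host-vertex> <theta>
#
# Inclusion orientations are stored as the angle theta from the host's
# first principal direction; the tangent vector is reconstructed on read
# from the (deterministic) mesh geometry.

fmt_g <- function(x) sprintf("%.17g", x)

#' Write a simulation frame in the native text format
#'
#' @param state a [simulation_state()] or [dts_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(state, path) {
  if (inherits(state, "dts_mesh")) state <- list(mesh = state, inclusions = NULL)
  mesh <- state$mesh
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("dtsframe 1", con)
  writeLines(paste("box", paste(fmt_g(mesh$box$L), collapse = " "),
                   paste(as.integer(mesh$box$periodic), collapse = " ")), con)
  nv <- nrow(mesh$vertices)
  writeLines(paste("vertices", nv), con)
  writeLines(paste(0:(nv - 1),
                   fmt_g(mesh$vertices[, 1]), fmt_g(mesh$vertices[, 2]),
                   fmt_g(mesh$vertices[, 3]), mesh$domain), con)
  nt <- nrow(mesh$triangles)
  writeLines(paste("triangles", nt), con)
  writeLines(paste(0:(nt - 1), mesh$triangles[, 1] - 1L,
                   mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  incl <- state$inclusions
  ni <- if (is.null(incl)) 0L else length(incl$vertex)
  writeLines(paste("inclusions", ni), con)
  if (ni > 0) {
    geom <- vertex_geometry(mesh)
    th <- vapply(seq_len(ni), function(i) {
      v <- incl$vertex[i]
      atan2(sum(incl$dir[i, ] * geom$T2[v, ]), sum(incl$dir[i, ] * geom$T1[v, ]))
    }, 0)
    # a state freshly parsed from file carries the exact stored angles; reuse
    # them (when still consistent with the orientations) so that
    # write(read(x)) is bit-identical to x
    if (!is.null(incl$theta) && length(incl$theta) == ni &&
        max(abs(incl$theta - th)) < 1e-9)
      th <- incl$theta
    nm <- vapply(incl$types, function(t) t$name, "")[incl$type]
    writeLines(paste(0:(ni - 1), nm, incl$vertex - 1L, fmt_g(th)), con)
  }
  invisible(path)
}

#' Read a native frame file
#'
#' @param path file path.
#' @param types list of [inclusion_type()] definitions matching the type
#'   names in the file (required when the file has inclusions).
#' @param pair_potentials optional list of [pair_potential()]s attached to
#'   the returned inclusions.
#' @param validate run [validate_mesh()] and stop on defects.
#' @return A list with `mesh` and `inclusions` (`NULL` when none).
#' @export
read_frame <- function(path, types = NULL, pair_potentials = list(),
                       validate = TRUE) {
  ln <- readLines(path)
  p <- 1L
  expect <- function(tag) {
    parts <- strsplit(trimws(ln[p]), "\\s+")[[1]]
    if (parts[1] != tag) stop(sprintf("%s:%d: expected '%s', got '%s'",
                                      path, p, tag, parts[1]))
    p <<- p + 1L
    parts[-1]
  }
  ver <- expect("dtsframe")
  if (ver[1] != "1") stop("unsupported frame format version: ", ver[1])
  bx <- as.numeric(expect("box"))
  box <- dts_box(bx[1:3], as.logical(bx[4:6]))
  nv <- as.integer(expect("vertices"))
  vrows <- do.call(rbind, strsplit(trimws(ln[p:(p + nv - 1)]), "\\s+"))
  p <- p + nv
  V <- matrix(as.numeric(vrows[, 2:4]), nv, 3)
  dom <- as.integer(vrows[, 5])
  nt <- as.integer(expect("triangles"))
  trows <- do.call(rbind, strsplit(trimws(ln[p:(p + nt - 1)]), "\\s+"))
  p <- p + nt
  Tr <- matrix(as.integer(trows[, 2:4]), nt, 3) + 1L
  mesh <- dts_mesh(V, Tr, box, domain = dom)
  if (validate) {
    rep <- validate_mesh(mesh)
    if (!rep$valid)
      stop(sprintf("%s: invalid mesh: %s", path,
                   paste(rep$defects, collapse = "; ")))
  }
  ni <- as.integer(expect("inclusions"))
  incl <- NULL
  if (ni > 0) {
    if (is.null(types)) stop("frame has inclusions but no `types` supplied")
    irows <- do.call(rbind, strsplit(trimws(ln[p:(p + ni - 1)]), "\\s+"))
    nm <- vapply(types, function(t) t$name, "")
    ity <- match(irows[, 2], nm)
    if (anyNA(ity)) stop("unknown inclusion type name in frame file")
    host <- as.integer(irows[, 3]) + 1L
    th <- as.numeric(irows[, 4])
    geom <- vertex_geometry(mesh)
    dir <- cos(th) * geom$T1[host, , drop = FALSE] +
      sin(th) * geom$T2[host, , drop = FALSE]
    incl <- dts_inclusions(host, ity, dir, types, pair_potentials)
    incl$theta <- th
  }
  list(mesh = mesh, inclusions = incl)
}

#' Export / import bare meshes as ascii PLY or OFF
#'
#' Minimal readers and writers for the two standard text mesh formats
#' (vertex positions and triangular faces only; inclusions travel in the
#' native format or config).
#'
#' @param mesh a [dts_mesh()].
#' @param path file path.
#' @param box a [dts_box()] to attach on import; a loose bounding box is
#'   built when `NULL`.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   [dts_mesh()].
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(fmt_g(mesh$vertices[, 1]), fmt_g(mesh$vertices[, 2]),
                   fmt_g(mesh$vertices[, 3])), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path, box = NULL) {
  ln <- readLines(path)
  if (ln[1] != "ply" || !grepl("ascii", ln[2]))
    stop("not an ascii PLY file")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)[1]))
  hdr <- which(ln == "end_header")[1]
  vrows <- do.call(rbind, strsplit(trimws(ln[(hdr + 1):(hdr + nv)]), "\\s+"))
  V <- matrix(as.numeric(vrows[, 1:3]), nv, 3)
  frows <- do.call(rbind, strsplit(trimws(ln[(hdr + nv + 1):(hdr + nv + nf)]), "\\s+"))
  if (any(frows[, 1] != "3")) stop("non-triangular face in PLY")
  Tr <- matrix(as.integer(frows[, 2:4]), nf, 3) + 1L
  if (is.null(box)) box <- loose_box(V)
  dts_mesh(V, Tr, box)
}

#' @rdname mesh_io
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  ed <- mesh_edges(mesh)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$triangles), nrow(ed)), con)
  writeLines(paste(fmt_g(mesh$vertices[, 1]), fmt_g(mesh$vertices[, 2]),
                   fmt_g(mesh$vertices[, 3])), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_off <- function(path, box = NULL) {
  ln <- readLines(path)
  if (trimws(ln[1]) != "OFF") stop("not an OFF file")
  cnt <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- cnt[1]; nf <- cnt[2]
  vrows <- do.call(rbind, strsplit(trimws(ln[3:(2 + nv)]), "\\s+"))
  V <- matrix(as.numeric(vrows[, 1:3]), nv, 3)
  frows <- do.call(rbind, strsplit(trimws(ln[(3 + nv):(2 + nv + nf)]), "\\s+"))
  if (any(frows[, 1] != "3")) stop("non-triangular face in OFF")
  Tr <- matrix(as.integer(frows[, 2:4]), nf, 3) + 1L
  if (is.null(box)) box <- loose_box(V)
  dts_mesh(V, Tr, box)
}

loose_box <- function(V) {
  ext <- apply(V, 2, function(x) diff(range(x)))
  dts_box(pmax(4 * ext, 1))
}

#' Load a full simulation state from a YAML configuration file
#'
#' The config has blocks `mesh` (a generator spec or a frame/PLY/OFF file),
#' `membrane`, `couplings`, `constraints`, `moves`, `inclusions` (type
#' definitions with a coverage fraction, plus optional pair potentials),
#' `confinement`, `force`, `frozen` and a mandatory `seed`. Inclusion
#' placement uses seeded uniform sampling of unoccupied vertices at the
#' requested coverage. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A [simulation_state()]; the seed is attached as attribute
#'   `seed`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("mesh", "membrane", "couplings", "constraints", "moves",
             "inclusions", "confinement", "force", "frozen", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a seed")
  set.seed(as.integer(cfg$seed))

  mc <- cfg$mesh
  mesh <- if (!is.null(mc$file)) {
    ext <- tolower(tools::file_ext(mc$file))
    fp <- if (file.exists(mc$file)) mc$file
          else file.path(dirname(path), mc$file)
    switch(ext,
           ply = read_ply(fp),
           off = read_off(fp),
           read_frame(fp)$mesh)
  } else {
    switch(mc$generator,
      flat = build_flat_grid(mc$nx, mc$ny, mc$spacing %||% 1.25),
      icosphere = build_icosphere(mc$subdivisions, mc$radius %||% NULL),
      tube = build_tube(mc$n_axial, mc$n_circ, mc$radius),
      torus = build_torus(mc$n_major, mc$n_minor, mc$R_major, mc$r_minor),
      stop("unknown mesh generator: ", mc$generator))
  }

  mb <- cfg$membrane %||% list()
  membrane <- membrane_params(kappa = mb$kappa %||% 20,
                              kappa_G = mb$kappa_G %||% 0,
                              C_bar = mb$C_bar %||% 0)
  cpl <- cfg$couplings %||% list()
  couplings <- ensemble_couplings(
    tension = cpl$tension, area = cpl$area, volume = cpl$volume,
    osmotic = cpl$osmotic, global_curvature = cpl$global_curvature)
  cs <- cfg$constraints %||% list()
  constraints <- dts_constraints(
    l_min = cs$l_min %||% 1, l_max = cs$l_max %||% sqrt(3),
    min_distance = cs$min_distance %||% 1,
    min_dihedral_cos = cs$min_dihedral_cos %||% 0)
  mv <- cfg$moves %||% list()
  moves <- move_params(delta = mv$delta %||% 0.1,
                       rotation = mv$rotation %||% (pi / 4),
                       box_amplitude = mv$box_amplitude %||% 0.01,
                       box_prob = mv$box_prob %||% 1)

  inclusions <- NULL
  ic <- cfg$inclusions
  if (!is.null(ic) && length(ic$types) > 0 && (ic$coverage %||% 0) > 0) {
    if (ic$coverage > 1) stop("inclusion coverage must be <= 1")
    types <- lapply(ic$types, function(t)
      inclusion_type(t$name, t$class,
                     dkappa = t$dkappa %||% 0, dkappa_G = t$dkappa_G %||% 0,
                     c0 = t$c0 %||% 0, k1 = t$k1 %||% 0, k2 = t$k2 %||% 0,
                     C_par0 = t$C_par0 %||% 0, C_perp0 = t$C_perp0 %||% 0))
    pots <- lapply(ic$pair_potentials %||% list(), function(p)
      pair_potential(p$type_i, p$type_j, A = p$A %||% 0, B = p$B %||% 0,
                     C = p$C %||% 0, n = p$n %||% 1,
                     Theta0 = p$Theta0 %||% 0, gamma0 = p$gamma0 %||% 0))
    inclusions <- place_inclusions(mesh, types, ic$coverage, pots)
  }

  confinement <- NULL
  cf <- cfg$confinement
  if (!is.null(cf)) {
    confinement <- switch(cf$kind,
      walls = conf_walls(cf$H, cf$z0 %||% 0),
      ellipsoid = conf_ellipsoid(unlist(cf$center), unlist(cf$semiaxes)),
      shell = conf_shell(unlist(cf$center), unlist(cf$semiaxes), cf$inner),
      block = conf_block(unlist(cf$xlim), unlist(cf$ylim), unlist(cf$zlim)),
      stop("unknown confinement kind: ", cf$kind))
  }
  force <- NULL
  if (!is.null(cfg$force))
    force <- external_force(cfg$force$vertex, unlist(cfg$force$anchor),
                            cfg$force$k)

  st <- simulation_state(mesh, membrane, couplings, constraints, moves,
                         inclusions, confinement, force,
                         frozen = isTRUE(cfg$frozen))
  attr(st, "seed") <- as.integer(cfg$seed)
  st
}
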