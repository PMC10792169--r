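# Metropolis Monte Carlo: state container, hard constraints, the engine
# driver, and reference single-move implementations.

#' Hard self-avoidance constraints
#'
#' Every edge length must stay inside `[l_min, l_max]`; any two vertices
#' (bonded or not) must be at least `min_distance` apart; adjacent triangle
#' normals must satisfy `cos(dihedral) >= min_dihedral_cos` (the default 0
#' rejects folds beyond 90 degrees). With `l_min = 1`, `l_max = sqrt(3)`
#' and the mild dihedral bound these constraints guarantee self-avoidance
#' of the surface.
#'
#' @param l_min,l_max edge-length window (DTS length units).
#' @param min_distance global minimum vertex-vertex distance.
#' @param min_dihedral_cos lower bound on the cosine of the angle between
#'   adjacent triangle normals.
#' @return An object of class `dts_constraints`.
#' @export
dts_constraints <- function(l_min = 1, l_max = sqrt(3), min_distance = 1,
                            min_dihedral_cos = 0) {
  if (l_min > l_max) stop("l_min must not exceed l_max")
  structure(list(l_min = l_min, l_max = l_max, min_distance = min_distance,
                 min_dihedral_cos = min_dihedral_cos),
            class = "dts_constraints")
}

#' Monte Carlo move amplitudes
#'
#' @param delta vertex displacement amplitude: proposals are uniform in a
#'   cube of side `2 * delta`.
#' @param rotation inclusion in-plane rotation amplitude (radians).
#' @param box_amplitude relative in-plane box rescale amplitude.
#' @param box_prob probability of one box trial per sweep (used only when
#'   the tension coupling is enabled).
#' @return An object of class `move_params`.
#' @export
move_params <- function(delta = 0.1, rotation = pi / 4,
                        box_amplitude = 0.01, box_prob = 1) {
  if (delta <= 0 || rotation <= 0 || box_amplitude <= 0)
    stop("move amplitudes must be positive")
  structure(list(delta = delta, rotation = rotation,
                 box_amplitude = box_amplitude, box_prob = box_prob),
            class = "move_params")
}

#' Confinement regions
#'
#' Vertices are rejected outside the confinement. `conf_walls` sandwiches
#' the membrane between two z walls a distance `H` apart; `conf_ellipsoid`
#' keeps the surface inside an ellipsoid; `conf_shell` between two scaled
#' copies of an ellipsoid; `conf_block` inside an axis-aligned box.
#'
#' @param H wall-to-wall distance (walls centred on `z0`).
#' @param z0 midplane of the walls.
#' @param center,semiaxes ellipsoid centre and semi-axes.
#' @param inner inner scale factor of the shell (in `(0, 1)`).
#' @param xlim,ylim,zlim block extents.
#' @return An object of class `dts_confinement`.
#' @name confinement
NULL

#' @rdname confinement
#' @export
conf_walls <- function(H, z0 = 0) {
  structure(list(kind = 1L, params = c(z0 - H / 2, z0 + H / 2)),
            class = "dts_confinement")
}

#' @rdname confinement
#' @export
conf_ellipsoid <- function(center, semiaxes) {
  structure(list(kind = 2L, params = c(center, semiaxes)),
            class = "dts_confinement")
}

#' @rdname confinement
#' @export
conf_shell <- function(center, semiaxes, inner) {
  stopifnot(inner > 0, inner < 1)
  structure(list(kind = 3L, params = c(center, semiaxes, inner)),
            class = "dts_confinement")
}

#' @rdname confinement
#' @export
conf_block <- function(xlim, ylim, zlim) {
  structure(list(kind = 4L, params = c(xlim, ylim, zlim)),
            class = "dts_confinement")
}

#' External harmonic force on a vertex
#'
#' Adds `(k/2) |r_v - anchor|^2` to the energy; stepping the anchor away
#' from the membrane pulls a tether.
#'
#' @param vertex target vertex index.
#' @param anchor 3-vector anchor point.
#' @param k spring constant (kBT per squared length unit, >= 0).
#' @return An object of class `external_force`.
#' @export
external_force <- function(vertex, anchor, k) {
  if (k < 0) stop("spring constant must be non-negative")
  structure(list(vertex = as.integer(vertex), anchor = as.numeric(anchor), k = k),
            class = "external_force")
}

#' Simulation state
#'
#' Bundles everything the sampler needs: mesh, geometry-independent model
#' parameters, couplings, constraints, move amplitudes, inclusions,
#' confinement, external force and the frozen-shape flag (when `TRUE`, only
#' inclusion moves run and the mesh never changes, for protein sorting on a
#' fixed shape).
#'
#' @param mesh a [dts_mesh()].
#' @param membrane a [membrane_params()].
#' @param couplings an [ensemble_couplings()].
#' @param constraints a [dts_constraints()].
#' @param moves a [move_params()].
#' @param inclusions a [dts_inclusions()] or `NULL`.
#' @param confinement a confinement object or `NULL`.
#' @param force an [external_force()] or `NULL`.
#' @param frozen logical; freeze the membrane shape.
#' @return An object of class `simulation_state`.
#' @export
simulation_state <- function(mesh, membrane = membrane_params(),
                             couplings = ensemble_couplings(),
                             constraints = dts_constraints(),
                             moves = move_params(),
                             inclusions = NULL, confinement = NULL,
                             force = NULL, frozen = FALSE) {
  if (!is.null(inclusions) && is.null(inclusions$dir)) {
    geom <- vertex_geometry(mesh)
    inclusions$dir <- geom$T1[inclusions$vertex, , drop = FALSE]
  }
  structure(list(mesh = mesh, membrane = membrane, couplings = couplings,
                 constraints = constraints, moves = moves,
                 inclusions = inclusions, confinement = confinement,
                 force = force, frozen = isTRUE(frozen), sweep = 0L),
            class = "simulation_state")
}

# assemble the engine configuration list from a state
engine_config <- function(state, beta = 1) {
  mesh <- state$mesh
  cp <- state$couplings
  incl <- state$inclusions
  if (is.null(incl)) {
    inc_cfg <- list(vertex = integer(0), type = integer(0),
                    dir = matrix(0, 0, 3), types = list())
  } else {
    nty <- length(incl$types)
    types <- lapply(incl$types, function(ty) list(
      cls = if (ty$class == "type1") 1L else 2L,
      dk = ty$dkappa, dkg = ty$dkappa_G, c0 = ty$c0,
      k1 = ty$k1, k2 = ty$k2, cpar0 = ty$C_par0, cperp0 = ty$C_perp0))
    names_ty <- vapply(incl$types, function(t) t$name, "")
    pots <- list()
    for (p in incl$pair_potentials) {
      i <- match(p$type_i, names_ty); j <- match(p$type_j, names_ty)
      if (is.na(i) || is.na(j)) stop("pair potential refers to unknown type")
      pots[[length(pots) + 1]] <- list(i = i, j = j, A = p$A, B = p$B, C = p$C,
                                       n = p$n, Theta0 = p$Theta0, gamma0 = p$gamma0)
    }
    inc_cfg <- list(vertex = incl$vertex, type = incl$type, dir = incl$dir,
                    types = types, pair_potentials = pots)
  }
  list(
    vertices = mesh$vertices, triangles = mesh$triangles,
    boxL = mesh$box$L, periodic = mesh$box$periodic,
    kappa = state$membrane$kappa, kappaG = state$membrane$kappa_G,
    Cbar = state$membrane$C_bar,
    constraints = list(lmin = state$constraints$l_min,
                       lmax = state$constraints$l_max,
                       mindist = state$constraints$min_distance,
                       mincos = state$constraints$min_dihedral_cos),
    moves = list(delta = state$moves$delta, rot_amp = state$moves$rotation,
                 box_amp = state$moves$box_amplitude,
                 box_prob = state$moves$box_prob),
    couplings = list(
      tension = list(enabled = !is.null(cp$tension),
                     tau = cp$tension$tau %||% 0),
      area = list(enabled = !is.null(cp$area),
                  KA = cp$area$K_A %||% 0, A0 = cp$area$A_0 %||% 1),
      volume = list(enabled = !is.null(cp$volume),
                    dP = cp$volume$dP %||% 0, K = cp$volume$K %||% 0,
                    vt = cp$volume$v_t %||% 1),
      osmotic = list(enabled = !is.null(cp$osmotic),
                     RT = cp$osmotic$RT %||% 0, cin = cp$osmotic$c_in %||% 0,
                     cout = cp$osmotic$c_out %||% 0,
                     Vini = cp$osmotic$V_ini %||% 1),
      global_curvature = list(enabled = !is.null(cp$global_curvature),
                              kr = cp$global_curvature$k_r %||% 0,
                              m0 = cp$global_curvature$m_0 %||% 0)),
    confinement = if (is.null(state$confinement)) list(kind = 0L)
                  else list(kind = state$confinement$kind,
                            params = state$confinement$params),
    force = if (is.null(state$force)) list(enabled = FALSE)
            else list(enabled = TRUE, vertex = state$force$vertex,
                      anchor = state$force$anchor, k = state$force$k),
    frozen = state$frozen, beta = beta,
    inclusions = inc_cfg)
}

#' Run Monte Carlo sweeps
#'
#' One sweep performs `N_T` Alexander link-flip trials, `N_v` vertex
#' displacement trials and `N_i` inclusion trials on uniformly random
#' targets, plus at most one box-rescale trial with probability
#' `moves$box_prob` when the tension coupling is enabled. In frozen-shape
#' mode only inclusion trials run. All randomness comes from R's RNG: call
#' `set.seed()` (or pass `seed`) for reproducible trajectories.
#'
#' @param state a [simulation_state()].
#' @param sweeps number of sweeps to run.
#' @param record_every store a frame (vertex positions, box) and an
#'   observables row every this many sweeps; 0 disables recording.
#' @param resync_every rebuild all caches from scratch every this many
#'   sweeps to keep incremental totals at full precision.
#' @param seed optional integer seed applied before running.
#' @param beta inverse temperature (1 by default; energies are in kBT).
#' @return A list with the updated `state`, `frames` (list of
#'   `list(sweep, vertices, boxL)`), `observables` (data.frame with sweep,
#'   total energy, area, volume, projected area, integrated mean curvature,
#'   pair energy), `acceptance` (rates per move class), and `energy`
#'   (final-term breakdown from the engine).
#' @export
run_mc <- function(state, sweeps, record_every = 0, resync_every = 256,
                   seed = NULL, beta = 1) {
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run(engine_config(state, beta), as.integer(sweeps),
                 as.integer(record_every), as.integer(resync_every))
  state$mesh$vertices <- res$vertices
  state$mesh$triangles <- res$triangles
  state$mesh$box$L <- res$boxL
  if (!is.null(state$inclusions)) {
    state$inclusions$vertex <- res$inclusion_vertex
    state$inclusions$dir <- res$inclusion_dir
    state$inclusions$theta <- NULL # stored file angles are stale now
  }
  state$sweep <- state$sweep + as.integer(sweeps)
  obs <- as.data.frame(res$observables)
  names(obs) <- c("sweep", "energy", "area", "volume", "projected_area",
                  "integrated_mean_curvature", "pair_energy")
  acc <- ifelse(res$tries > 0, res$acc / res$tries, NA_real_)
  names(acc) <- names(res$acc)
  list(state = state, frames = res$frames, observables = obs,
       acceptance = acc, trials = res$tries, energy = res$energy)
}

#' Audit the hard constraints of a state
#'
#' Brute-force check (no cell list) of the edge window, global minimum
#' vertex distance, dihedral bound and confinement; intended for tests and
#' frame audits.
#'
#' @param state a [simulation_state()].
#' @return A list of violation counts; `total` is their sum.
#' @export
check_constraints <- function(state) {
  mesh <- state$mesh
  cons <- state$constraints
  ed <- mesh_edges(mesh)
  n_edge <- sum(ed$length < cons$l_min - 1e-9 | ed$length > cons$l_max + 1e-9)
  V <- mesh$vertices
  nv <- nrow(V)
  n_close <- 0L
  md2 <- (cons$min_distance - 1e-9)^2
  for (i in seq_len(nv - 1)) {
    d <- min_image(V[(i + 1):nv, , drop = FALSE] -
                   matrix(V[i, ], nv - i, 3, byrow = TRUE), mesh$box)
    n_close <- n_close + sum(rowSums(d^2) < md2)
  }
  tg <- triangle_geometry(mesh)
  cosd <- rowSums(tg$normal[ed$t1, , drop = FALSE] * tg$normal[ed$t2, , drop = FALSE])
  n_dihedral <- sum(cosd < cons$min_dihedral_cos - 1e-9)
  n_conf <- 0L
  if (!is.null(state$confinement)) {
    cf <- state$confinement
    inside <- apply(V, 1, function(p) point_confined(p, cf))
    n_conf <- sum(!inside)
  }
  out <- list(edge_window = n_edge, min_distance = n_close,
              dihedral = n_dihedral, confinement = n_conf)
  out$total <- n_edge + n_close + n_dihedral + n_conf
  out
}

point_confined <- function(p, cf) {
  pr <- cf$params
  switch(cf$kind,
    p[3] >= pr[1] && p[3] <= pr[2],
    sum(((p - pr[1:3]) / pr[4:6])^2) <= 1,
    {
      r <- sqrt(sum(((p - pr[1:3]) / pr[4:6])^2))
      r >= pr[7] && r <= 1
    },
    p[1] >= pr[1] && p[1] <= pr[2] && p[2] >= pr[3] && p[2] <= pr[4] &&
      p[3] >= pr[5] && p[3] <= pr[6])
}

# ---- reference single-move implementations (R, full-recompute dE) -------
# These mirror the engine's trial moves one at a time for small systems and
# tests; the compiled sweep driver is the production path.

state_constraints_ok <- function(state) check_constraints(state)$total == 0

#' Single vertex-displacement trial (reference implementation)
#'
#' Proposes a uniform displacement in a cube of side `2 * delta` (or the
#' given displacement), rejects immediately on any hard-constraint or
#' confinement violation, otherwise accepts with the Metropolis probability
#' `min(1, exp(-beta * dE))` where `dE` is the full energy difference.
#'
#' @param state a [simulation_state()].
#' @param v vertex index.
#' @param displacement optional fixed 3-vector proposal (for tests).
#' @param beta inverse temperature; `Inf` gives a zero-temperature quench
#'   (accept only `dE <= 0`).
#' @return A list with `state`, `accepted`, and `dE` (NA when rejected by
#'   constraints).
#' @export
attempt_vertex_move <- function(state, v, displacement = NULL, beta = 1) {
  if (state$frozen) stop("vertex moves are disabled in frozen-shape mode")
  if (is.null(displacement))
    displacement <- runif(3, -state$moves$delta, state$moves$delta)
  new_state <- state
  new_state$mesh$vertices[v, ] <- state$mesh$vertices[v, ] + displacement
  if (!state_constraints_ok(new_state))
    return(list(state = state, accepted = FALSE, dE = NA_real_))
  e0 <- total_energy(state)
  e1 <- total_energy(new_state)
  dE <- as.numeric(e1) - as.numeric(e0)
  acc <- if (is.infinite(beta)) dE <= 0 else dE <= 0 || runif(1) < exp(-beta * dE)
  if (acc) list(state = new_state, accepted = TRUE, dE = dE)
  else list(state = state, accepted = FALSE, dE = dE)
}

#' Single Alexander link-flip trial (reference implementation)
#'
#' Performs the topological flip via [flip_edge_topology()], rejects if the
#' flip is illegal or the new edge violates the length window or dihedral
#' bound, otherwise applies the Metropolis rule to the energy difference.
#'
#' @param state a [simulation_state()].
#' @param a,b endpoints of the edge to flip.
#' @param beta inverse temperature.
#' @return A list with `state`, `accepted`, `dE`.
#' @export
attempt_alexander_flip <- function(state, a, b, beta = 1) {
  if (state$frozen) stop("flips are disabled in frozen-shape mode")
  new_state <- state
  flipped <- tryCatch(flip_edge_topology(state$mesh, a, b),
                      error = function(e) NULL)
  if (is.null(flipped)) return(list(state = state, accepted = FALSE, dE = NA_real_))
  new_state$mesh <- flipped
  if (!state_constraints_ok(new_state))
    return(list(state = state, accepted = FALSE, dE = NA_real_))
  dE <- as.numeric(total_energy(new_state)) - as.numeric(total_energy(state))
  acc <- if (is.infinite(beta)) dE <= 0 else dE <= 0 || runif(1) < exp(-beta * dE)
  if (acc) list(state = new_state, accepted = TRUE, dE = dE)
  else list(state = state, accepted = FALSE, dE = dE)
}

#' Single inclusion trial (reference implementation)
#'
#' With probability one half an in-plane rotation of the orientation by a
#' uniform angle within the rotation amplitude, otherwise a hop to a
#' uniformly chosen adjacent vertex (rejected outright if occupied) with
#' the orientation parallel-transported along the connecting edge.
#'
#' @param state a [simulation_state()].
#' @param i inclusion index.
#' @param beta inverse temperature.
#' @return A list with `state`, `accepted`, `dE`.
#' @export
attempt_inclusion_move <- function(state, i, beta = 1) {
  incl <- state$inclusions
  if (is.null(incl) || i > length(incl$vertex)) stop("no such inclusion")
  geom <- vertex_geometry(state$mesh)
  u <- incl$vertex[i]
  new_state <- state
  if (runif(1) < 0.5) {
    ang <- runif(1, -state$moves$rotation, state$moves$rotation)
    n <- geom$normal[u, ]
    d <- incl$dir[i, ]
    nxd <- c(n[2] * d[3] - n[3] * d[2], n[3] * d[1] - n[1] * d[3],
             n[1] * d[2] - n[2] * d[1])
    new_state$inclusions$dir[i, ] <- cos(ang) * d + sin(ang) * nxd
  } else {
    ring <- one_ring(state$mesh, u)
    w <- ring[sample.int(length(ring), 1)]
    if (w %in% incl$vertex)
      return(list(state = state, accepted = FALSE, dE = NA_real_))
    new_state$inclusions$vertex[i] <- w
    new_state$inclusions$dir[i, ] <-
      parallel_transport(state$mesh, geom, u, w, incl$dir[i, ])
  }
  dE <- as.numeric(total_energy(new_state, geom)) -
    as.numeric(total_energy(state, geom))
  acc <- if (is.infinite(beta)) dE <= 0 else dE <= 0 || runif(1) < exp(-beta * dE)
  if (acc) list(state = new_state, accepted = TRUE, dE = dE)
  else list(state = state, accepted = FALSE, dE = dE)
}

#' Single box-rescale trial (reference implementation)
#'
#' Proposes an isotropic in-plane rescale `Lx, Ly -> lambda Lx, lambda Ly`
#' with all x, y coordinates rescaled affinely; rejects on any constraint
#' violation; accepts with probability
#' `min(1, exp(-beta dE + N_v log lambda^2))` where the logarithmic term is
#' the coordinate-rescaling Jacobian.
#'
#' @param state a [simulation_state()] with the tension coupling enabled.
#' @param lambda optional fixed rescale factor (for tests).
#' @param beta inverse temperature.
#' @return A list with `state`, `accepted`, `dE`.
#' @export
attempt_box_resize <- function(state, lambda = NULL, beta = 1) {
  if (is.null(state$couplings$tension))
    stop("box moves require the tension coupling")
  if (!all(state$mesh$box$periodic[1:2]))
    stop("box moves require an x,y-periodic frame")
  if (is.null(lambda))
    lambda <- 1 + runif(1, -state$moves$box_amplitude, state$moves$box_amplitude)
  new_state <- state
  new_state$mesh$vertices[, 1:2] <- state$mesh$vertices[, 1:2] * lambda
  new_state$mesh$box$L[1:2] <- state$mesh$box$L[1:2] * lambda
  if (!state_constraints_ok(new_state))
    return(list(state = state, accepted = FALSE, dE = NA_real_))
  dE <- as.numeric(total_energy(new_state)) - as.numeric(total_energy(state))
  logacc <- -beta * dE + nrow(state$mesh$vertices) * log(lambda^2)
  acc <- logacc >= 0 || runif(1) < exp(logacc)
  if (acc) list(state = new_state, accepted = TRUE, dE = dE)
  else list(state = state, accepted = FALSE, dE = dE)
}

#' One reference Monte Carlo sweep
#'
#' R-level sweep with the same composition as the engine (`N_T` flips,
#' `N_v` vertex moves, `N_i` inclusion moves, possible box trial); useful
#' for small systems and pedagogical runs. Use [run_mc()] for production.
#'
#' @param state a [simulation_state()].
#' @param beta inverse temperature.
#' @return A list with `state` and `accepted` counts per move class.
#' @export
mc_sweep <- function(state, beta = 1) {
  acc <- c(flip = 0L, vertex = 0L, inclusion = 0L, box = 0L)
  ed <- mesh_edges(state$mesh)
  nT <- nrow(state$mesh$triangles)
  nV <- nrow(state$mesh$vertices)
  nI <- if (is.null(state$inclusions)) 0L else length(state$inclusions$vertex)
  if (!state$frozen) {
    for (k in seq_len(nT)) {
      e <- sample.int(nrow(ed), 1)
      r <- attempt_alexander_flip(state, ed$v1[e], ed$v2[e], beta)
      state <- r$state
      if (r$accepted) {
        acc["flip"] <- acc["flip"] + 1L
        ed <- mesh_edges(state$mesh)
      }
    }
    for (k in seq_len(nV)) {
      r <- attempt_vertex_move(state, sample.int(nV, 1), beta = beta)
      state <- r$state
      if (r$accepted) acc["vertex"] <- acc["vertex"] + 1L
    }
  }
  for (k in seq_len(nI)) {
    r <- attempt_inclusion_move(state, sample.int(nI, 1), beta = beta)
    state <- r$state
    if (r$accepted) acc["inclusion"] <- acc["inclusion"] + 1L
  }
  if (!state$frozen && !is.null(state$couplings$tension) &&
      runif(1) < state$moves$box_prob) {
    r <- attempt_box_resize(state, beta = beta)
    state <- r$state
    if (r$accepted) acc["box"] <- acc["box"] + 1L
  }
  list(state = state, accepted = acc)
}
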