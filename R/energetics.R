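# Membrane-level energies and system couplings. All energies in kBT,
# lengths in the DTS unit length.

#' Membrane elastic parameters
#'
#' @param kappa bending rigidity (kBT).
#' @param kappa_G Gaussian modulus (kBT); enters the bending energy with a
#'   minus sign, so a positive `kappa_G` lowers the energy of a sphere by
#'   `4 * pi * kappa_G`.
#' @param C_bar spontaneous membrane curvature (1 / length unit).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(kappa = 20, kappa_G = 0, C_bar = 0) {
  if (kappa < 0) stop("kappa must be non-negative")
  structure(list(kappa = kappa, kappa_G = kappa_G, C_bar = C_bar),
            class = "membrane_params")
}

#' Ensemble couplings
#'
#' Collects the optional system-level energy terms; each is independently
#' enabled by supplying its block.
#'
#' @param tension `list(tau = , box_prob = , box_amp = )` couples the energy
#'   to `-tau * A_p` (projected area) and enables the box-rescaling move;
#'   `tau` in kBT per squared length unit.
#' @param area `list(K_A = , A_0 = )` harmonic area constraint
#'   `N_T * K_A/2 * (A/A_0 - 1)^2`.
#' @param volume `list(dP = , K = , v_t = )` first- and second-order volume
#'   coupling `-dP*V + K/2 * (V/V_0 - v_t)^2`, `V_0 = A^{3/2} / (6 sqrt(pi))`.
#' @param osmotic `list(RT = , c_in = , c_out = , V_ini = )` van 't Hoff
#'   osmotic term `-RT * (c_in * V_ini * log(V / V_ini) - c_out * (V - V_ini))`.
#' @param global_curvature `list(k_r = , m_0 = )` couples the integrated
#'   mean curvature `M = sum(2 H_v A_v)` to `k_r/(2A) * (M - m_0 A)^2`.
#' @return An object of class `ensemble_couplings`.
#' @export
ensemble_couplings <- function(tension = NULL, area = NULL, volume = NULL,
                               osmotic = NULL, global_curvature = NULL) {
  if (!is.null(volume)) {
    vt <- volume$v_t %||% 1
    if (vt <= 0 || vt > 1) stop("targeted reduced volume v_t must be in (0, 1]")
  }
  if (!is.null(area) && (area$A_0 %||% 1) <= 0) stop("A_0 must be positive")
  if (!is.null(osmotic) && (osmotic$V_ini %||% 1) <= 0) stop("V_ini must be positive")
  structure(list(tension = tension, area = area, volume = volume,
                 osmotic = osmotic, global_curvature = global_curvature),
            class = "ensemble_couplings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Helfrich bending energy
#'
#' `E_b = sum_v ( kappa/2 * (2 H_v - C_bar)^2 - kappa_G * K_v ) * A_v` with
#' `2 H_v = c1 + c2` and `K_v = c1 * c2`.
#'
#' @param mesh a [dts_mesh()] (used only for dimension checks).
#' @param geom its [vertex_geometry()].
#' @param params a [membrane_params()].
#' @return Total bending energy (kBT) with per-vertex contributions in
#'   attribute `per_vertex`.
#' @export
bending_energy <- function(mesh, geom, params) {
  twoH <- geom$c1 + geom$c2
  K <- geom$c1 * geom$c2
  ev <- (params$kappa / 2 * (twoH - params$C_bar)^2 - params$kappa_G * K) * geom$area
  structure(sum(ev), per_vertex = ev)
}

#' Harmonic surface-area constraint energy
#'
#' `E_A = N_T * K_A/2 * (A/A_0 - 1)^2` where `A` is the total triangle area.
#'
#' @param mesh a [dts_mesh()].
#' @param K_A compressibility modulus (kBT).
#' @param A_0 target area.
#' @return Energy in kBT.
#' @export
area_coupling_energy <- function(mesh, K_A, A_0) {
  if (K_A < 0) stop("K_A must be non-negative")
  if (A_0 <= 0) stop("A_0 must be positive")
  A <- sum(triangle_geometry(mesh)$area)
  nrow(mesh$triangles) * K_A / 2 * (A / A_0 - 1)^2
}

#' Enclosed volume of a closed mesh
#'
#' Signed divergence-theorem sum over triangles; positive for outward
#' orientation.
#'
#' @param mesh a closed (non-periodic) [dts_mesh()].
#' @return Volume in cubic length units.
#' @export
enclosed_volume <- function(mesh) {
  if (any(mesh$box$periodic))
    stop("enclosed volume is defined only for closed (non-periodic) meshes")
  ed <- mesh_edges(mesh)
  if (any(is.na(ed$t2))) stop("mesh has boundary edges; volume undefined")
  sum(triangle_geometry(mesh)$volume)
}

#' Volume coupling energy
#'
#' `E_v = -dP * V + K/2 * (V/V_0 - v_t)^2` with
#' `V_0 = A^{3/2} / (6 sqrt(pi))`, the volume of the sphere with area `A`.
#'
#' @param V enclosed volume.
#' @param A total surface area.
#' @param dP inside-outside pressure difference.
#' @param K volume compressibility modulus.
#' @param v_t targeted reduced volume in (0, 1].
#' @return Energy in kBT.
#' @export
volume_coupling_energy <- function(V, A, dP = 0, K = 0, v_t = 1) {
  if (K > 0 && A <= 0) stop("A must be positive when K > 0")
  second <- if (K != 0) {
    V0 <- A^1.5 / (6 * sqrt(pi))
    K / 2 * (V / V0 - v_t)^2
  } else 0
  -dP * V + second
}

#' Osmotic (van 't Hoff) volume energy
#'
#' `dE = -RT * (c_in * V_ini * log(V / V_ini) - c_out * (V - V_ini))`; its
#' stationary point sits where the interior concentration
#' `c_in * V_ini / V` equals `c_out`.
#'
#' @param V current volume (> 0).
#' @param RT energy scale (kBT units).
#' @param c_in,c_out effective inside / outside solute concentrations.
#' @param V_ini initial volume (> 0).
#' @return Energy in kBT.
#' @export
osmotic_energy <- function(V, RT, c_in, c_out, V_ini) {
  if (V <= 0 || V_ini <= 0) stop("volumes must be positive")
  -RT * (c_in * V_ini * log(V / V_ini) - c_out * (V - V_ini))
}

#' Global-curvature (area-difference) energy
#'
#' `E_s = k_r / (2 A) * (M - m_0 A)^2` with `M = sum_v 2 H_v A_v`. Because
#' the monolayer area difference is proportional to `M`, this term can be
#' used to control area difference as well.
#'
#' @param mesh a [dts_mesh()].
#' @param geom its [vertex_geometry()].
#' @param k_r coupling constant (kBT).
#' @param m_0 target average global curvature (1 / length unit).
#' @return Energy in kBT.
#' @export
global_curvature_energy <- function(mesh, geom, k_r, m_0) {
  A <- geom$total_area
  if (A <= 0) stop("total area must be positive")
  M <- sum((geom$c1 + geom$c2) * geom$area)
  k_r / (2 * A) * (M - m_0 * A)^2
}

#' Frame-tension energy of a periodically framed membrane
#'
#' `E_tau = -tau * A_p` with projected area `A_p = Lx * Ly`.
#'
#' @param box a [dts_box()] periodic in x and y.
#' @param tau frame tension (kBT per squared length unit).
#' @return Energy in kBT.
#' @export
frame_tension_energy <- function(box, tau) {
  if (!box$periodic[1] || !box$periodic[2])
    stop("frame tension requires x,y-periodic box")
  -tau * box$L[1] * box$L[2]
}

#' Harmonic external force energy
#'
#' `(k/2) |r_v - anchor|^2` for the target vertex; moving the anchor over
#' time pulls a membrane tether.
#'
#' @param mesh a [dts_mesh()].
#' @param force an [external_force()] or `NULL`.
#' @return Energy in kBT.
#' @export
harmonic_force_energy <- function(mesh, force) {
  if (is.null(force)) return(0)
  d <- mesh$vertices[force$vertex, ] - force$anchor
  force$k / 2 * sum(d^2)
}

#' Total energy of a simulation state
#'
#' Sum of all enabled terms: bending, inclusion site and pair energies,
#' tension, area, volume, osmotic, global-curvature couplings and the
#' external harmonic force.
#'
#' @param state a [simulation_state()].
#' @param geom optional precomputed [vertex_geometry()]; recomputed when
#'   `NULL`.
#' @return Total energy (kBT), with attribute `breakdown` listing each term.
#' @export
total_energy <- function(state, geom = NULL) {
  mesh <- state$mesh
  if (is.null(geom)) geom <- vertex_geometry(mesh)
  cp <- state$couplings
  bd <- list(
    bending = as.numeric(bending_energy(mesh, geom, state$membrane)),
    inclusion = inclusion_field_energy(state, geom),
    tension = if (!is.null(cp$tension)) frame_tension_energy(mesh$box, cp$tension$tau) else 0,
    area = if (!is.null(cp$area)) {
      nrow(mesh$triangles) * cp$area$K_A / 2 * (geom$total_area / cp$area$A_0 - 1)^2
    } else 0,
    volume = if (!is.null(cp$volume)) {
      volume_coupling_energy(geom$volume, geom$total_area,
                             cp$volume$dP %||% 0, cp$volume$K %||% 0,
                             cp$volume$v_t %||% 1)
    } else 0,
    osmotic = if (!is.null(cp$osmotic)) {
      osmotic_energy(geom$volume, cp$osmotic$RT, cp$osmotic$c_in,
                     cp$osmotic$c_out, cp$osmotic$V_ini)
    } else 0,
    global_curvature = if (!is.null(cp$global_curvature)) {
      global_curvature_energy(mesh, geom, cp$global_curvature$k_r,
                              cp$global_curvature$m_0)
    } else 0,
    force = harmonic_force_energy(mesh, state$force))
  structure(sum(unlist(bd)), breakdown = bd)
}
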