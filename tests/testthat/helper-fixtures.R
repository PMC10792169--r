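# Shared fixtures, built in code. Sizes are kept small: the geometry
# estimator converges from subdivision 2-3 onward and the samplers are
# exercised at the smallest meshes that leave room for flips.

fix_sphere <- function(subdiv = 3) build_icosphere(subdiv)

fix_torus <- function() build_torus(60, 16, 12.8, 3.2)

# radius chosen so circumferential chords equal the lattice spacing
fix_tube <- function(n = 12, spacing = 1.25)
  build_tube(n, n, radius = spacing / (2 * sin(pi / n)))

fix_flat <- function(n = 8, spacing = 1.25) build_flat_grid(n, n, spacing)

sphere_radius <- function(mesh) mean(sqrt(rowSums(mesh$vertices^2)))

# vertex valences (number of neighbours)
valences <- function(mesh) {
  ed <- mesh_edges(mesh)
  tabulate(c(ed$v1, ed$v2), nbins = nrow(mesh$vertices))
}

# analytic area and volume of a prolate spheroid with semi-axes (a, a, c)
prolate_area <- function(a, c) {
  e <- sqrt(1 - a^2 / c^2)
  2 * pi * a^2 * (1 + c / (a * e) * asin(e))
}
prolate_volume <- function(a, c) 4 / 3 * pi * a^2 * c
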