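Package: dtsmc
Title: Dynamically Triangulated Surface Monte Carlo for Fluid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mesoscale Monte Carlo simulation of fluid lipid membranes as
    dynamically triangulated surfaces. Vertices represent membrane patches of
    hundreds of lipids; a discrete shape operator supplies per-vertex
    principal curvatures and directions, a Helfrich curvature Hamiltonian
    with optional tension, area, volume, osmotic and global-curvature
    couplings governs the energetics, and a Metropolis move set (vertex
    displacements, Alexander link flips, inclusion moves, box rescaling)
    samples the Boltzmann distribution under hard self-avoidance
    constraints. Orientable protein inclusions with isotropic or anisotropic
    curvature coupling and nearest-neighbour pair interactions can decorate
    the surface. Analysis tools include the height-undulation spectrum with
    bending-rigidity and tension fits, reduced volume, and the mapping of
    the simulation length unit to nanometres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
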