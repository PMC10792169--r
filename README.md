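# dtsmc

Mesoscale Monte Carlo simulation of fluid membranes as **dynamically
triangulated surfaces** (DTS), for membrane biophysicists studying shape
remodeling, curvature elasticity, and protein organization on membranes —
vesicle shape transitions, tether pulling, undulation spectra, and the
sorting of curvature-coupled proteins on fixed or evolving shapes.

## The model

A membrane is a triangulated closed surface whose vertices each represent a
patch of hundreds of lipids. Fluidity comes from Alexander link flips
(resampling the triangulation), and the energetics is a discretized
Helfrich Hamiltonian

$$E_b=\sum_v\Big\{\tfrac{\kappa}{2}(2H_v-\bar C)^2-\kappa_G K_v\Big\}A_v,$$

with per-vertex curvatures from an edge-dihedral shape operator, plus
optional couplings: frame tension $-\tau A_p$ with a box-rescaling move,
harmonic area and volume constraints, van 't Hoff osmotic pressure, a
global-curvature (area-difference) term, confinements, and harmonic point
forces for tether pulling. Proteins are vertex-bound oriented inclusions —
isotropic (type 1) or anisotropic (type 2, with preferred curvatures along
and perpendicular to their in-plane orientation $\hat D$) — interacting on
adjacent vertices through
$-A_{ij}-B_{ij}\cos[n(\Theta-\Theta_0)]-C_{ij}\cos(\gamma-\gamma_0)$,
with parallel transport keeping orientations meaningful on curved surfaces.
Metropolis sampling respects hard self-avoidance constraints (edge window
$[1,\sqrt3]\,l_{dts}$, global hard core, dihedral bound). Energies are in
$k_BT$, lengths in the DTS unit $l_{dts}$. The Monte Carlo core is
compiled (Rcpp) with incremental energy evaluation; everything is driven
from R.

## Worked example: a tensionless framed membrane

```r
library(dtsmc)

mesh <- build_flat_grid(16, 16, spacing = 1.25)
mesh
#> dts_mesh: 256 vertices, 768 edges, 512 triangles
#>   Euler characteristic 0; box [20 17.3 60] periodic [T T F]

state <- simulation_state(
  mesh,
  membrane  = membrane_params(kappa = 20),           # bending rigidity, kBT
  couplings = ensemble_couplings(tension = list(tau = 0)))

res <- run_mc(state, 5000, record_every = 50, seed = 1)  # burn-in
round(res$acceptance, 3)
#>      flip    vertex inclusion       box
#>     0.023     0.477        NA     0.056

res  <- run_mc(res$state, 20000, record_every = 50)      # production
spec <- undulation_spectrum(res$frames)
fit  <- fit_spectrum(spec)
sprintf("kappa_eff = %.1f kBT; large-q slope = %.2f",
        fit$kappa_eff, spectrum_large_q_slope(spec))
#> "kappa_eff = 18.9 kBT; large-q slope = -4.07"
```

The spectrum of the thermalized membrane follows
$\langle u(q)u(-q)\rangle = 1/(\kappa_{\rm eff}q^4+\tau q^2)$: the fitted
effective rigidity recovers the input $\kappa=20\,k_BT$ to within the
statistical error of this short run, and the tensionless tail decays as
$q^{-4}$ (slope $-4$). With tension the small-$q$ branch crosses over to
$q^{-2}$.

Converting model units to physical ones via a protein's lateral size:

```r
mp <- length_mapping(7.2)   # cholera/Shiga toxin B subunit, ~7.2 nm
sprintf("l_dts = %.1f nm; c0 = 0.4/l_dts = %.3f 1/nm",
        mp$l_dts_nm, mp$curvature_to_nm(0.4))
#> "l_dts = 6.9 nm; c0 = 0.4/l_dts = 0.058 1/nm"
```

Other entry points: `build_icosphere()` / `build_tube()` / `build_torus()`
for vesicle, tube and genus-1 fixtures; `place_inclusions()` +
`inclusion_type()` + `pair_potential()` for protein fields;
`conf_walls()` and friends for confinement; `external_force()` for tether
pulling; `reduced_volume()`, `vertex_geometry()`, `total_energy()` for
observables; `write_frame()` / `read_frame()` / `write_ply()` for I/O;
`load_config()` for YAML-driven runs; `frozen = TRUE` in
`simulation_state()` for protein sorting on a static shape.

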