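---
title: "Dynamically triangulated membrane Monte Carlo: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamically triangulated membrane Monte Carlo: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtsmc)
```

## The model

`dtsmc` simulates fluid lipid membranes at the mesoscale as dynamically
triangulated surfaces (DTS). Each vertex represents a membrane patch of
hundreds of lipids; triangles tile a closed orientable surface (a vesicle,
a torus, a tube, or a sheet closed through periodic boundaries). Fluidity
-- the defining property of a lipid bilayer -- is obtained by resampling
the connectivity with Alexander link flips: the shared edge of two adjacent
triangles is swapped to the opposite diagonal of their quadrilateral, so
neighbour relations diffuse even though the numbers of vertices, edges and
triangles stay constant.

Energies are measured in units of $k_BT$ and lengths in the DTS unit
length $l_{dts}$, defined as the minimum distance allowed between any two
vertices. The elastic backbone is a discretized Helfrich Hamiltonian

$$E_b=\sum_{v}\Big\{\tfrac{\kappa}{2}\,(2H_v-\bar C)^2-\kappa_G K_v\Big\}A_v,$$

with per-vertex mean curvature $2H_v=c_{1,v}+c_{2,v}$, Gaussian curvature
$K_v=c_{1,v}c_{2,v}$ and patch area $A_v$. The Gaussian term carries a
minus sign so that a positive $\kappa_G$ is reported; by Gauss--Bonnet its
sum is topological, which the test suite verifies to 1% on spheres and 5%
on tori. Optional system-level couplings:

* **frame tension** $E_\tau=-\tau A_p$ with the projected area
  $A_p=L_xL_y$ of an $x,y$-periodic frame, sampled with a box-rescaling
  move ($(N_v,\tau,T)$ ensemble);
* **area constraint** $E_A=N_T\frac{K_A}{2}(A/A_0-1)^2$;
* **volume coupling** $E_v=-\Delta P\,V+\frac{K}{2}(V/V_0-v_t)^2$ with
  $V_0=A^{3/2}/(6\sqrt\pi)$, the volume of the sphere with the same area,
  so $V/V_0$ is the reduced volume $v$;
* **osmotic pressure** (van 't Hoff)
  $\Delta E=-RT[\bar c_{in}V_{ini}\ln(V/V_{ini})-\bar c_{out}(V-V_{ini})]$,
  stationary where the interior concentration has diluted to the exterior
  one;
* **global curvature / area difference**
  $E_s=\frac{k_r}{2A}(M-m_0A)^2$ with $M=\sum_v 2H_vA_v$; because the
  monolayer area difference is proportional to $M$, the same term controls
  area difference;
* a **harmonic point force** $\frac{k}{2}|\mathbf r_v-\mathbf a|^2$ on a
  chosen vertex, which grows a membrane tether when the anchor is placed
  away from the surface.

## Discrete geometry

Per-vertex curvatures come from an edge-dihedral shape operator. Each
interior edge $e$ carries the integrated curvature tensor
$h_e\,\hat b_e\otimes\hat b_e$ with $h_e=2\lVert e\rVert\sin(\theta_e/2)$,
where $\theta_e$ is the angle between the two face normals, signed
positive when the faces tilt away from each other (ridge) and negative in
a valley, and $\hat b_e$ is the edge binormal. A vertex accumulates half
of each incident edge's tensor, divides by
$A_v=\frac13\sum_{T\ni v}A_T$, projects onto the tangent plane of the
area-weighted vertex normal and diagonalizes the resulting $2\times2$
operator, giving $c_1\ge c_2$ and orthonormal principal directions
$\hat T_1,\hat T_2$. Spheres with outward normals have positive
curvatures.

Accuracy, measured against analytic surfaces (the test battery): on a
subdivision-3 icosphere the per-vertex mean curvature is within 2% of
$1/R$ at all regular (6-valent) vertices and the area-weighted mean within
0.3%; on a lattice cylinder $c_1$ is within 3% of $1/\rho$ with the first
principal direction circumferential to better than 5 degrees. Two
systematic effects are worth knowing:

* the 12 pentavalent vertices of any icosahedral tessellation are true
  cone points of the polyhedron -- their discrete curvature is genuinely
  concentrated (about 15% above $1/R$, and the angle-defect estimator
  shows the same concentration), which no consistent local polyhedral
  estimator removes;
* at near-umbilic points the ordering $c_1\ge c_2$ repels the two
  eigenvalues symmetrically about their (accurate) mean, by about
  $\pm6\%$ on the icosphere. Quantities built from $H$ and $K$ are
  unaffected at leading order. At exactly umbilic points
  ($|c_1-c_2|<10^{-9}$) the principal frame is degenerate and $\hat T_1$
  falls back to the tangent projection of a fixed axis; inclusion
  energies are insensitive to the choice there because
  $C_\parallel=C_\perp$.

Positions are kept unwrapped; every displacement, triangle area and normal
uses minimum-image differences on periodic axes, so the geometry is
seamless across the box.

## Protein inclusions

An inclusion occupies one vertex (at most one per vertex -- this occupancy
rule is the in-plane excluded volume) and carries a tangent unit
orientation $\hat D$. Type-1 (isotropic, toxin-like) inclusions add
$\{2\Delta\kappa H^2-2(\Delta\kappa+\kappa)c_0H-\Delta\kappa_G K\}A_v$;
type-2 (anisotropic, BAR/dynamin-like) inclusions add
$\{\frac{k_1}{2}(C_\parallel-C_{\parallel0})^2+\frac{k_2}{2}(C_\perp-C_{\perp0})^2\}A_v$
with the directional curvatures from Euler's formula
$C_\parallel=c_1\cos^2\theta+c_2\sin^2\theta$,
$C_\perp=c_1\sin^2\theta+c_2\cos^2\theta$,
$\cos\theta=\hat D\cdot\hat T_1$. The energy depends on $\cos^2\theta$
only, so $\hat D\to-\hat D$ is a symmetry (nematic order).

Neighbouring inclusions (interaction range: one edge) interact through the
lowest-order Fourier potential
$e=-A_{ij}-B_{ij}\cos[n(\Theta-\Theta_0)]-C_{ij}\cos(\gamma-\gamma_0)$.
$\Theta=\Theta_2-\Theta_1$ compares the two orientations against the
tangent-plane projections of the line connecting the hosts -- the same
construction used to parallel-transport $\hat D$ when an inclusion hops,
so an orientation "kept constant relative to the connector" contributes
no spurious angle. $\gamma$ is the angle between the host normals, signed
by the tip-to-tip rule: positive when the normal tips are farther apart
than the edge length (ridge), negative in a valley; with $\gamma_0\ne0$ an
adjacent pair imprints curvature, which is how dimerization-driven
curvature generation is modelled. The branch convention of the individual
$\Theta_k$ is immaterial because only $\cos[n(\Theta-\Theta_0)]$ enters.

Small proteins (below the membrane thickness, under about 4 nm) would
require several inclusions per vertex and an explicit excluded-volume
energy; this regime is rejected at configuration time.

## Monte Carlo sampling

One sweep performs $N_T$ link-flip trials, $N_v$ vertex-displacement
trials and $N_i$ inclusion trials on uniformly random targets, plus at
most one box-rescale trial (probability `box_prob`, only in the tension
ensemble). Hard constraints are checked before any energy is computed and
reject the trial outright:

* every edge length inside $[l_{min},l_{max}]$ with the defaults
  $l_{min}=1\,l_{dts}$, $l_{max}=\sqrt3\,l_{dts}$;
* a global hard core of $l_{dts}$ between **all** vertex pairs, enforced
  with a spatial hash of cell size $\ge l_{dts}$ (constant cost per
  trial);
* a mild dihedral bound: adjacent face normals must keep
  $\cos\theta\ge0$ by default (folds beyond 90 degrees rejected);
* optional confinement (sandwiching walls, ellipsoid, ellipsoidal shell,
  block).

Together the edge window and hard core guarantee self-avoidance of the
surface. Surviving trials are accepted with the Metropolis probability
$\min(1,e^{-\beta\Delta E})$, where $\Delta E$ is evaluated incrementally
over the exact dependency region (a vertex's geometry depends only on its
incident triangles, so a move refreshes the moved vertex plus its one
ring; a flip refreshes the four quad vertices). Running totals of area,
volume, $M$ and the energy terms are updated with the move and
re-synchronized from scratch every `resync_every` sweeps (default 256) so
the incremental bookkeeping never drifts; the test suite checks
incremental-vs-full agreement to $10^{-8}$ after $10^3$ accepted moves
with no mid-run resync.

The box move rescales $L_x,L_y\to\lambda L_x,\lambda L_y$ with all $x,y$
coordinates scaled affinely and accepts with
$\min(1,e^{-\beta\Delta E+N_v\ln\lambda^2})$ -- the logarithmic term is
the Jacobian of the coordinate rescaling. Inclusion trials split evenly
between in-plane rotations (uniform angle within $\pm\pi/4$ by default)
and hops to a uniformly drawn adjacent vertex (rejected if occupied) with
parallel-transported orientation; the even split keeps the proposal
symmetric. In frozen-shape mode only inclusion trials run and the mesh is
bit-identical before and after -- the mode used to sort proteins on a
fixed (e.g. experimentally derived) shape, where the static mesh is
exempt from the edge-window audit since it never moves.

Default amplitudes ($\delta=0.1\,l_{dts}$ displacements, $\pi/4$
rotations, 1% box rescale) give 30--60% acceptance on the test fixtures
and are configurable. All randomness flows from R's RNG, so a single
`set.seed()` (or the mandatory `seed` key of a config file) fixes the
whole trajectory; trajectories are also invariant under save/resume
because move targets are drawn through connectivity-independent keys
(triangle slots and sorted neighbour lists).

## The undulation spectrum and its estimators

A thermalized framed membrane follows
$\langle u(q)u(-q)\rangle=1/(\kappa_{\rm eff}q^4+\tau q^2)$: $q^{-4}$
scaling where bending dominates and $q^{-2}$ where tension does.
`undulation_spectrum()` offers two estimators, and the distinction
matters:

* **`"surface"`** (default): the piecewise-linear height field of the
  triangulation -- the membrane surface itself -- is sampled exactly on an
  oversampled regular grid (3x the vertex Nyquist by default) and
  Fourier-transformed. No irregular-sampling artefacts; this estimator
  reproduces $1/(\kappa q^4)$ to a few percent up to $0.8$ of the vertex
  Nyquist wavevector on simulated tensionless membranes.
* **`"vertex"`**: amplitudes estimated from the vertex heights alone by
  least-squares regression on the plane-wave basis (the Lomb--Scargle
  treatment of unevenly sampled data). A naive discrete Fourier sum is
  *not* usable here: fluid-mesh vertices are irregularly placed, plane
  waves are not orthogonal over them, and the large long-wavelength
  amplitudes leak into the steep tail and floor it. The regression removes
  the leakage exactly and is unbiased for point-sampled heights -- the
  synthetic-data tests recover $\kappa$ to well under 10% and $\tau$
  within 25%.

The two differ near the lattice cutoff for a physical reason: the
one-ring-averaged shape operator is softer than the continuum $\kappa
q^4$ at short wavelengths (measured on imposed single modes: the discrete
bending energy falls to 0.39x continuum at $q\,a\approx2.8$), so the
*vertex* field genuinely over-fluctuates there by equipartition, while
the *surface* spectrum attenuates those same wavelengths through the
linear interpolant. The surface estimator is the package's default
because the physical claim -- the membrane's height spectrum -- refers to
the surface, not to the vertex point set.

`fit_spectrum()` fits $1/S$ against $(q^4,q^2)$ by weighted least squares
(inverse-variance weights $\propto n\,S^2$; unweighted fitting would let
the smallest, noisiest high-$q$ values dominate), constrains
$\kappa_{\rm eff}\ge0$, and reports the log--log slope;
`spectrum_large_q_slope()` fits the slope over the upper half of the
resolved $q$ range. `synthetic_spectrum_frames()` draws independent
Gaussian modes with the exact model covariance on the vertices of a
framed mesh; it emulates equilibrium height statistics only -- no
in-plane vertex diffusion, no connectivity resampling, no anharmonicity
-- so passing recovery tests validates the estimator and fit machinery,
not the sampler (the sampler is validated separately against the slope
and the analytic energy batteries).

## Problem sizes and numerical choices

The test batteries use the smallest fixtures at which the estimators
converge: subdivision-3 icospheres (642 vertices) for analytic geometry
and energies, a 60x16 torus (960 vertices; its minor radius of
$3.2\,l_{dts}$ is the smallest that keeps all edges inside the window
while resolving the minor curvature), 16x16 framed membranes with
$5\times10^4$ production sweeps after $10^4$ burn-in for the tensionless
spectrum, $2\times10^4$ sweeps for vesicle volume targeting, and $10^4$
sweep constraint audits. On one CPU core the full suite runs in a few
minutes.

The volume-targeting experiments run in the coupling-dominated regime
($K=10^5\,k_BT$ against $\kappa=20\,k_BT$). This is a deliberate choice:
the harmonic volume term is a soft constraint, and for it to pin the
reduced volume to $v_t\pm0.05$ it must dominate the competing elastic
scales. Quantitatively, $K=10^3$ supplies only
$\frac{K}{2}(v-v_t)^2\approx38\,k_BT$ of drive over the whole range
$v\in[0.7,1]$, against an approximately $100$--$180\,k_BT$ bending cost
of deflating a $\kappa=20$ vesicle -- the vesicle then stays quasi-spherical;
lowering $\kappa$ instead hands control to thermal wrinkling, which pulls
$v$ to about 0.8 regardless of target. With $K=10^5$ the targets 0.7 and
0.9 are met within 0.02--0.05 in $2\times10^4$ sweeps and the deflated
vesicle leaves the spherical shape class (gyration anisotropy > 2),
consistent with the prolate/oblate/stomatocyte sequence expected at
decreasing reduced volume.

Other numerical details, for the record: degenerate (zero-area) trial
triangles are rejected as constraint violations; the convexity sign of an
edge dihedral is decided by $(\,\hat n_1-\hat n_2)\cdot(\mathbf
c_1-\mathbf c_2)$ with $\mathbf c_i$ the face centroids (equivalent to
the tip-to-tip rule); inclusion orientations are re-projected onto the
tangent plane whenever their host's normal changes; flips are refused
when they would duplicate an edge or leave an endpoint with fewer than
three neighbours; and the native frame format stores full-precision
(`%.17g`) numbers with 0-based indices so text round trips are
bit-exact.

## What the generators emulate, and limitations

The built-in generators (flat periodic sheet, icosphere, tube, torus)
provide idealized starting shapes; arbitrary closed meshes, including
high-genus ones, are accepted through the native format or PLY/OFF as
long as `validate_mesh()` passes. Real data differ from all synthetic
fixtures in ways the tests cannot probe: experimental meshes carry
irregular valence distributions and curvature at the resolution limit,
and mapping physical proteins onto single-vertex inclusions compresses
their anisotropy into two preferred curvatures and one symmetry order.

Hard limitations of the model as implemented: fixed topology (no fission,
fusion or pore formation), no open edges, no vertex insertion or removal,
Monte Carlo time is not physical time (no hydrodynamics), and a single
temperature per run (no replica exchange). Curvature energies beyond
quadratic order in the principal curvatures are not implemented.
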