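---
title: "Modeling fibrin accumulation on flow-diverter wires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fibrin accumulation on flow-diverter wires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Flow-diverting (FD) stents treat intracranial aneurysms by covering the
aneurysm orifice with a braided screen of fine metallic wires. Occlusion
develops partly because fibrin — the polymerized product of the plasma
protein fibrinogen — accumulates on the wires, progressively sealing the
device cells and choking the inflow jet. `fdfibrin` simulates this process
in idealized vessel and aneurysm geometries: a quasi-steady incompressible
flow solver with a Darcy clot-feedback force, loosely coupled to a
finite-volume transport–reaction solver for six plasma species.

# The model

## Flow

Plasma is an incompressible Newtonian fluid (default density
$\rho = 1030\,\mathrm{kg/m^3}$, viscosity $\mu = 1.3\times10^{-3}\,$Pa·s —
standard plasma values; they are configurable). The accumulated clot acts on
the momentum balance as a porous (Darcy) sink

$$F = -\pi_c\,\phi(C_{Fb}/C_{Fb0})\,u,$$

where $C_{Fb}$ is the bounded-fibrin concentration, $C_{Fb0}$ a threshold
below which the force vanishes, $\pi_c$ an inverse-permeability scale and
$\phi(x) = x^n/(1+x^n)$ the Hill switch used throughout the package for
smooth thresholding. The per-element shear-stress magnitude is
$\tau = \mu\dot\gamma$ with $\dot\gamma = \sqrt{2\,e_{ij}e_{ij}}$ the second
invariant of the strain-rate tensor.

## Species and reactions

Six species are tracked (µM): prothrombin (PT), antithrombin (AT), thrombin
(Th), fibrinogen (Fg), free fibrin (Fn) and bounded fibrin (Fb). The reduced
network is:

* thrombin is produced from prothrombin near thrombogenic wires,
  $K_{wt}\,w(r)\,C_{PT}$, and neutralized by antithrombin,
  $K_{at}\,C_{AT}\,C_{Th}$;
* fibrin is cleaved from fibrinogen by thrombin,
  $K_{th}\,C_{Th}\,C_{Fg}/(K_m + C_{Fg})$, and independently wherever shear
  exceeds a threshold, $K_{ss}\,\phi(\tau/\tau_0)\,C_{Fg}$ (the latter
  pathway reflects the in-vitro observation that fibrinogen concentrate
  deposits fibrin under flow without any thrombin);
* free fibrin adheres to wires, $K_{wa}\,w(r)\,C_{Fn}$, and to
  already-bounded fibrin, $K_b\,\bar C_{Fb}\,C_{Fn}$.

Here $w(r)$ is the wire-proximity switch. We implement it as
$w(r) = 1 - \phi(r/r_0)$, which is $\approx 1$ on the wire surface and
decays beyond $r_0$; the literal increasing form $\phi(r/r_0)$ — which
contradicts the stated physics of wire-stimulated production — is available
via `reaction_params(wire_switch_literal = TRUE)` for exact reproduction of
the printed source terms. The Michaelis-type constant $K_m$ is applied
literally in the fibrinogen denominator $(K_m + C_{Fg})$.

Two algebraic identities pin the network down and are enforced by tests:
$S_{Fg} + S_{Fn} + S_{Fb} = 0$ (the fibrin family only converts, never
appears or disappears) and $S_{PT} + S_{Th} = S_{AT}$.

The adhesion term uses $\bar C_{Fb}$, the average of bounded fibrin over all
elements whose centroids lie within a fibre length of the element. This is
the mechanism by which a clot spreads across a device cell: without it,
bounded fibrin could never seed a neighbouring element and the device would
never occlude.

## Units

Concentrations are micromolar throughout the package (all
concentration-bearing rate constants are µM-based); geometry, time and
stress are SI. Fibrinogen mass concentrations are converted at the config
boundary (`fibrinogen_mg_dl_to_uM()`, 340 kDa).

# Numerics

## Flow solver

Linear (P1) finite elements on unstructured tetrahedra, advanced to steady
state by a fractional-step scheme: implicit viscous + porous velocity
prediction (the porous term dominates in clotted regions and makes the
prediction well-conditioned exactly where the physics is stiff), a
pressure-Poisson solve (Cholesky-factored once per mesh), and an explicit
velocity correction. Advection is explicit, so the pseudo-timestep obeys
$\Delta t < h/|u|$. Convergence is declared when the per-step velocity
change $\max|u^{n+1}-u^n|$ (a velocity — the same scale the coupling
criterion uses) falls below $\epsilon_1 = 10^{-4}\,$m/s.

On coarse meshes the cell Péclet number far exceeds the Galerkin stability
limit, so an element artificial viscosity
$\mu_{art} = \tfrac12 c\,\rho\,|\bar u_e| h_e$ (default $c = 1$) stabilizes
the advective operator. The Poiseuille benchmarks are insensitive to this:
at prescribed flow the parabolic profile is viscosity-independent, and the
shear evaluation always uses the physical $\mu$.

Boundary conditions: parabolic inlet profile (by mean velocity, or by flow
rate with exact discrete rescaling), traction-free outlet with pressure
anchored there, no-slip on walls and on immersed-boundary nodes. A
pressure-driven inlet (`flow_bc(type = "pressure")`) exists because a
velocity-Dirichlet inlet prescribes the flux: a uniformly clotted domain
cannot show a flow collapse under prescribed flux (mass conservation), so
the occlusion limit is assessed at fixed driving pressure, which is the
physically meaningful comparison.

## Transport solver

Cell-centered finite volumes on the same mesh. Convective face fluxes are
first-order upwind by default; a MUSCL reconstruction with the minmod
limiter ("tvd") is available and reduces smooth-profile advection error.
Diffusive fluxes are two-point central with the face-average diffusivity
(protein diffusivities default to $5\times10^{-11}\,\mathrm{m^2/s}$). A
divergence source $C_k Q_k$ absorbs the residual non-solenoidality of the
interpolated face velocities; combined with upwinding this yields a
monotone scheme (no new extrema, non-increasing total variation). Explicit
Runge–Kutta (2-stage midpoint by default) with the timestep
$\Delta t = \mathrm{Cou}\cdot\min(h/|u|,\ h^2/2D,\ V/Q,\ \tau_{react})$,
where the reaction time is the sink-only linearization $C_i/|S_i|$ for
$S_i < 0$ (equal to $1/k$ for a linear sink, independently of $C$).
Negative concentrations from explicit integration of stiff sinks are
clipped to zero and the clipped mass is accumulated and reported.

Bounded fibrin carries no convective or diffusive fluxes and no divergence
source; inlet faces carry convective flux only (prescribed upstream value),
outlet faces use the interior upwind value, and walls and wire-blocked
faces carry nothing.

## Staggered coupling

The flow is frozen while transport advances. The re-solve criterion
monitors the porosity-force change since the last flow solution,
$\delta R = \Delta t\,\max_k |\pi_c(\phi_k^{now}-\phi_k^{ref})\,u_k|/\rho$,
and triggers a (warm-started) re-solve when $\delta R \ge \epsilon_2 =
10^{-3}$. The flow residual therefore never exceeds $\epsilon_2$ between
solves and is below $\epsilon_1$ immediately after each solve. Runs
checkpoint to RDS files and restart bit-exactly (the pipeline contains no
randomness).

# Meshes and devices

No external mesher is assumed. Tubes and boxes are body-fitted structured
meshes (elliptic square-to-disc mapping, Kuhn 6-tet splitting; boundary
nodes lie exactly on the cylinder). The sidewall aneurysm — a torus-segment
parent vessel unioned with a spherical sac seated on the outer bend — is an
implicit-geometry voxel-tet mesh; its boundary is stair-stepped at the
voxel scale, the analytic neck-plane disc is stored for inflow metrics, and
both vessel ends are tagged liberally across the ragged end zones so no
spurious no-slip constriction forms there. Local refinement around wires
uses conformity-preserving longest-edge (Rivara) bisection; three
bisections per level halve the local element size.

Braided devices are pairs of counter-rotating helix families on the
deployment cylinder (each wire at half the braid angle from the device
axis, so larger braid angles give more circumferential wires and smaller
pores), sampled as overlapping spheres for edge-cut detection. For the
straight-tube benchmark the device is a flat screen of two crossing wire
families with a prescribed cell angle. Immersed-boundary handling tags
nodes inside wires (plus cut-edge endpoints nearest the wire) for no-slip
and builds the exact element-centroid distance field `r` used by the
proximity switch.

# Desk-scale choices

The package targets meshes of $10^4$–$5\times10^4$ elements that run on one
CPU in minutes (the acceptance runs use a 300 µm tube at ~9 k elements and
a sidewall model at ~17 k elements). Several choices follow from this scale
deliberately; each is a documented coarse-graining, not a change of model:

* **Rate constants.** The originating experiments' parameter tables are not
  public, and such constants are in any case tuned to reproduce observed
  accumulation patterns. The shipped defaults (see `reaction_params()`) are
  literature-consistent in structure and scaled so the occlusion dynamics
  complete within seconds of simulated time at desk resolution; they were
  frozen after qualitative calibration against the behaviors the scenarios
  must reproduce (distal-first neck accumulation, monotone inflow decay,
  denser screens accumulating more fibrin).
* **Wire-proximity threshold.** $r_0$ is set per scenario to
  $\max(2 r_{wire},\ \mathrm{median}\ h)$: if the proximity region does not
  span at least one cell, the device is kinetically invisible.
* **Wire-scale shear closure.** A coarse cell cannot resolve the shear at a
  wire surface. Inside wire-containing cells the reactions see
  $\tau_{eff} = \max(\tau_{resolved},\ \mu |u|/\delta)$ with $\delta$ a
  pore half-width (default $10^{-4}$ m). On the near-resolved tube meshes
  this is inert (the resolved shear dominates); on the coarse sidewall mesh
  it restores the distal/proximal contrast of the orifice jet that actually
  localizes deposition.
* **Fibre length.** The neighbourhood-average radius is raised to at least
  two median element sizes — below one cell the spreading mechanism is
  inert, and without it device occlusion cannot develop at all.
* **Orifice-only wires in the sidewall scenarios.** Wall-apposed wire
  segments sit inside the unresolved near-wall boundary layer beneath a
  clot layer of wire-scale thickness. Representing them with cell-thick
  porous blocks would artificially narrow the parent lumen (and push flow
  *into* the sac); the deployed device is therefore trimmed to its
  orifice-spanning portion (`trim_wires_to_orifice()`).
* **Scenario end times.** The experimental time points are unlabeled in the
  source figures; desk-scale runs use a fraction of a second to a couple of
  seconds of simulated (global) time under the accelerated kinetics, which
  is where the qualitative sequence (production, distal onset, spreading,
  inflow decay) plays out. End time is a configuration knob.

# What the scenarios do and do not show

The four packaged scenarios (`tube90`, `tube150`, `sidewall_plasma`,
`sidewall_fibrinogen_only`) are synthetic reconstructions of idealized
bench experiments: exact geometric primitives, steady prescribed inflow,
fresh inlet concentrations and a clean initial state. Passing their checks
shows that the coupled model reproduces the *mechanistic* signatures —
fibrin-family conservation, shear- and proximity-gated production, distal
onset at the orifice, monotone occlusion and flow decay. It does not
demonstrate patient-specific fidelity: no pulsatility, no platelets or
erythrocytes, no fibrin detachment (absent from the model by design — total
bounded fibrin is monotonically non-decreasing), no vessel compliance, and
boundary layers and pore-scale flow are represented through the closures
above rather than resolved.

# Numerical edge cases

* Degenerate meshes (non-positive volumes, non-manifold faces) are rejected
  at construction; element orientation is auto-corrected.
* Refinement tie-breaks (equal longest edges) are resolved on the edge key,
  deterministically and consistently across elements.
* An empty wire set yields an infinite distance field and no immersed
  boundary; a zero fibre length makes the neighbourhood average the
  identity.
* The distance field is truncated at a cutoff (default 40 wire radii plus
  two element sizes) far beyond the reach of the proximity switch; points
  beyond the cutoff carry the cutoff value.
* Pressure solves require at least one outlet node; meshes without an
  outlet are rejected as singular.
* All file outputs (VTU/VTP/CSV/JSON) are plain text; checkpoints are RDS.

# Known limitations

The stair-stepped sidewall boundary exaggerates wall shear locally and
makes absolute pressure drops unreliable (relative, monotone trends are
what the scenarios assert). The P1–P1 projection carries the usual
approximate-projection boundary error, visible as a few-percent bias in
wall-adjacent shear (the package's `tube_wall_shear()` estimator
compensates by chord-midpoint extrapolation and by excluding boundary
slivers whose nodes are all wall-pinned). At effective desk-scale Reynolds
numbers the inertial character of the inflow jet is heavily damped by the
stabilizing viscosity; the wire-scale closure, not resolved inertia,
carries the deposition asymmetry.
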