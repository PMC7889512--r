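---
title: "Methods: coupled xylem-phloem transport on procedural vein networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled xylem-phloem transport on procedural vein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

veinflow simulates steady-state water and sucrose transport in an angiosperm
leaf represented as two superposed conduit networks — xylem (water only) and
phloem (water plus sucrose) — connected node-by-node by semipermeable cross
conduits. This vignette documents the model equations, the procedural
geometry, the numerical method, and the known limitations, so that every
number the package produces can be traced to an explicit assumption.

## 1. Model

Each leaf is discretised as a square lattice of nodes inside a parameterised
outline, plus one external petiole node where boundary conditions are
imposed. Every node carries three unknowns: xylem hydraulic pressure
$p^{x}_{ij}$ (MPa), phloem hydraulic pressure $p^{f}_{ij}$ (MPa), and phloem
sucrose concentration $C_{ij}$ (mol m$^{-3}$). Fluxes are node-centric:
a flux written for node $ij$ and neighbour $d$ is positive when it enters
$ij$.

**Xylem water.** Darcy flow along conduits plus a fixed per-area
transpirational efflux and the cross-conduit exchange:

$$\sum_d K^{x}_{d,ij}\,(p^{x}_d - p^{x}_{ij}) \;+\; E\,a_{ij} \;+\; F^{c}_{ij} = 0,$$

with $E < 0$ for a transpiring leaf and $a_{ij}$ the nodal area.

**Cross conduit.** An ideal semipermeable membrane (reflection coefficient
$\sigma_c = 1$) between the xylem and phloem partners of a node:

$$F^{c}_{ij} = K_c\left[(p^{f}_{ij} - \sigma_c R T C_{ij}) - p^{x}_{ij}\right].$$

With positive sucrose concentration this term is negative at equal
pressures: the osmotic pull of the phloem sap draws water out of the xylem —
the classical Münch mechanism driving phloem bulk flow.

**Phloem water.** Darcy/osmotic flow along sieve conduits, with lateral
reflection coefficient $\sigma = 0$ by default (solutes pass freely between
phloem nodes, so the lateral osmotic term vanishes), minus the cross flux:

$$\sum_d K^{f}_{d,ij}\left[(p^{f}_d - p^{f}_{ij}) - \sigma R T (C_d - C_{ij})\right] \;-\; F^{c}_{ij} = 0.$$

**Sucrose.** Convection with the phloem water plus Fickian diffusion, plus a
fixed per-area loading source:

$$\sum_d \left[(1 - \sigma)\, v_\mu\, F^{f}_{d,ij}\, C^{conv} + G_{d,ij}(C_d - C_{ij})\right] \;+\; \Lambda\, a_{ij} = 0,$$

where $v_\mu$ is the molal volume of water (converting the water flux in
mmol s$^{-1}$ to a volumetric flux) and $G = D_{su} A_{f} / \ell$ is the
diffusive conductance of a conduit of cross-section $A_f$ and length $\ell$.
Two conventions for the convected concentration $C^{conv}$ are provided
(section 5).

**Boundary conditions.** At the petiole node: Dirichlet pressures
$p^{x} = 0.00$ MPa and $p^{f} = 0.20$ MPa (defaults), and a zero-gradient
sucrose condition $C_{pet} = C_{first}$ against the adjacent main-vein node.

**Default parameters** (all configurable through `model_params()`):

| quantity | symbol | default | units |
|---|---|---|---|
| temperature | $T$ | 293 | K |
| gas constant | $R$ | 8.31e-6 | MPa m$^3$ mol$^{-1}$ K$^{-1}$ |
| sucrose diffusivity | $D_{su}$ | 5.22e-10 | m$^2$ s$^{-1}$ |
| molal volume of water | $v_\mu$ | 18.00e-9 | m$^3$ mmol$^{-1}$ |
| cross-conduit conductance | $K_c$ | 0.50 | mmol s$^{-1}$ MPa$^{-1}$ |
| transpiration rate | $E$ | -2.00 | mmol s$^{-1}$ m$^{-2}$ |
| sucrose loading rate | $\Lambda$ | 2.78e-7 | mol s$^{-1}$ m$^{-2}$ |
| phloem/xylem conductance ratio | — | 3/100 | — |
| conductivities, orders 1–5 | — | 1e-2, 5e-4, 6e-5, 4e-5, 4e-6 | m mmol s$^{-1}$ MPa$^{-1}$ |
| conduit diameters, orders 1–5 | — | 15.50, 11.30, 7.50, 7.20, 4.34 | µm |

Per-edge conductances are conductivity divided by edge length; phloem
conductance is the xylem value times the phloem factor; sucrose loading can
optionally follow a linear base-to-tip gradient (±50% of the mean) that
preserves the leaf-area-weighted mean.

## 2. Leaf shapes and lattice

Three lanceolate outlines share a blade area of 73.35 cm² but differ in
proportion: reference (16.00 × 6.47 cm), wide (12.8 × 8.09 cm) and narrow
(19.2 × 5.39 cm). The half-width profile is the smooth family
$w(z) = (W/2)\sin(\pi z / L)^q$, with the exponent $q$ fitted by root
finding (via the closed form of $\int_0^\pi \sin^q t\,dt$) so the outline
area matches the target exactly; $q \approx 0.68$ for the reference leaf.

Nodes sit on a square lattice (default spacing 2 mm) at positions strictly
inside the outline; the petiole node is external, linked to the first
main-vein node by a 5-mm order-1 conduit. Nodal areas are computed by
clipping each lattice cell against the outline with a 15-point Simpson rule
per row band; bands partition $[0, L]$ and marginal cells absorb the blade
sliver beyond the outermost node of their row, so nodal areas sum to the
blade area (closure better than 1%, enforced by tests).

The 2-mm default was chosen because it keeps the largest problem under
~6,000 unknowns (about two seconds per solve on one CPU), and places the
order-3 lattice veins 12 mm apart, commensurate with the ~10-mm second-order
vein intervals. Angle-response *magnitudes* depend on this choice — a finer
background lattice shortcuts more of the second-order transport — so sweep
spreads should be compared across configurations only at fixed spacing.

## 3. Vein hierarchy

**Orders 1, 3, 4, 5 (background lattice).** The main vein (order 1) runs the
symmetry axis. Lattice rows and columns are numbered from the base/axis;
every 6th line carries an order-3 vein, the remaining even lines order 4 and
odd lines order 5, so *every* axial lattice edge between adjacent inside
nodes carries a vein order and the areoles are bounded by order-4/5 veins.

**Order 2 (angled veins).** Second-order veins attach to the main vein at a
series of rows (first attachment 5 mm from the petiole) and run toward the
margin at an angle $\theta$ measured from the perpendicular to the main
vein. Thirteen canonical angles are supported — 0.00° to 75.96° — chosen so
$\tan\theta = p/q$ with small integers; each vein is then rasterized exactly
as a repeating Bresenham staircase of $\min(p,q)$ diagonal plus $|p-q|$
axial lattice steps per period (when $p > q$ the period is rotated to start
on a diagonal step so the vein leaves the main vein immediately). Where a
second-order staircase overlaps a background vein, the lowest order (highest
conductivity) wins.

Veins are laid out in mirrored left/right pairs, which makes the edge set —
and therefore the solved fields under uniform forcing — exactly symmetric
about the main vein; this symmetry is a tested invariant.

**Constant total length.** The default experimental control keeps the total
second-order length at 0.74 ± 0.01 m for every shape and angle, so angle
responses are not confounded by added conductive material. The attachment
intervals alternate between two values $(L_{v1}, L_{v2})$ found by integer
search over lattice-snapped pairs. Because that two-parameter family leaves
gaps in the achievable totals (the total jumps by a whole vein pair), a
second greedy stage nudges individual attachment rows by one or two lattice
units — each nudge changes a vein pair's length by twice the local
half-width difference, giving near-millimetre control. The search minimises
the deviation from the target and aborts if the tolerance cannot be met. A
`constant_spacing` mode (fixed interval, floating total) is also provided.

## 4. Numerical method

The unknown vector $x = [p^x; p^f; C]$ stacks the three fields (petiole node
last). The solver is a damped Newton iteration with an analytically
assembled sparse Jacobian (`Matrix`), a backtracking line search on the
scaled residual norm, and an LU solve with sparse-QR fallback per step.

**Scaling.** Residual rows are scaled by per-equation magnitudes built from
the node's conductance degree times a pressure scale (0.1 MPa), the
cross-conduit coefficients, and the forcing magnitudes ($|E\,a|$,
$|\Lambda\,a|$); concentration columns are scaled by 100 mol m$^{-3}$.
Convergence requires the maximum scaled residual below $10^{-10}$
(configurable).

**Continuation.** If plain Newton fails, a homotopy ramps $K_c$ and
$\Lambda$ from zero (where the system is linear: decoupled Darcy networks)
to their targets in five stages, restarting Newton from each intermediate
solution. In practice the production runs converge in 4–6 plain Newton
iterations without continuation.

**Independent oracle.** `brute_force_oracle()` solves the same residual
system by a deliberately different route — dense Newton with a central
finite-difference Jacobian (`pracma::jacobian`) inside the same homotopy —
and the test suite requires agreement to $10^{-8}$ relative on batches of
random toy networks, plus exact agreement with a pen-and-paper telescoped
solution for uniform transpiring chains (`xylem_chain_closed_form()`).

**A structural degeneracy worth knowing.** With $K_c = 0$ the phloem
pressure field is uniform, so phloem flow — and with it convective sucrose
export — is identically zero, while the zero-gradient petiole condition
also kills diffusive export. Loaded sucrose then has no exit: the system is
inconsistent for $\Lambda > 0$ and singular (concentration level
undetermined) for $\Lambda = 0$. `solve_steady()` refuses to converge in
this regime by design; the cross-conduit coupling is not an optional
refinement but the mechanism that closes the sucrose budget. The
decoupled-network *limit* is explored with the small-but-positive value
$K_c = 5\times10^{-4}$ instead.

## 5. Sucrose convection schemes

Two conventions for the convected concentration are implemented:

- `"literal"` (default): the convective factor is always the centre node's
  concentration $C_{ij}$. This matches the stated balance form, but the flux
  is not pairwise antisymmetric: summed over an edge's two orientations it
  leaves $v_\mu F (C_{ij} - C_d)$, so total export at the petiole falls
  short of total loading. The deficit is reported per solve
  (`sucrose_conservation_gap`; about half the loading at default
  parameters) rather than hidden.
- `"upwind"`: donor-cell convection — the flux carries the concentration of
  the node the water flows *from*. This is pairwise antisymmetric and closes
  the sucrose budget to machine precision (also tested), at the price of
  slightly different concentration levels (~8% higher leaf averages).

The headline indices are computed under the literal scheme; the upwind
scheme quantifies the scheme sensitivity.

## 6. Whole-leaf indices and experiments

`area_average()` is the arithmetic mean of a field over inside nodes (the
petiole is excluded). `sweep_vein_angle()` rebuilds the layout and re-solves
for each of the 13 angles; `find_peak_angle()` reports the sampled-grid
argmax without interpolation; `variation_metric()` is a pluggable percentage
spread, $100(\max - \min)/|\text{mean}|$ by default, since no single
definition of "degree of variation" is canonical.
`pressure_difference_map()` gives the per-node driving force
$p^x - (p^f - R T C)$, the circulation diagnostic whose sign marks where
water crosses from xylem to phloem.

Typical problem sizes at the 2-mm default: 1,827–1,837 inside nodes per
shape (~5,500 unknowns), ~3,600 edges; a layout builds in ~2 s and a solve
takes ~2 s on one CPU. A full 3-shape × 13-angle sweep is ~39 solves.

```{r example}
library(veinflow)
lay <- build_vein_layout(make_leaf_shape("reference"), spacing = 0.002,
                         theta = 45)
fit <- solve_steady(lay, model_params())
glance(fit)
autoplot(fit, field = "C")
sw <- sweep_vein_angle(make_leaf_shape("narrow"))
find_peak_angle(sw)
```

## 7. Limitations

- The background lattice spacing is a free discretisation parameter; peak
  *locations* on the 13-angle grid are stable to it in our checks, but
  spread magnitudes are not, and one reported peak (wide leaf at 5× order-2
  conductivity) sits on a broad plateau where the argmax is sensitive to
  discretisation details.
- Steady state only; no time dependence, no water storage, no
  concentration-dependent viscosity or conductances.
- The leaf is flat and 2-D; order-2 veins are mirrored pairs on a perfect
  lattice, not measured venation.
- The literal convection scheme does not conserve sucrose (section 5); the
  gap is reported, and the conservative upwind alternative is one switch
  away.
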