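---
title: "Mechanical models and quantification methods in morphomech"
author: "morphomech authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical models and quantification methods in morphomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphomech)
```

## The problem

A monoclonal epithelial colony growing on a flat substrate does not stay a
monolayer forever. In solid-like (jammed) cell sheets, growth against
interfacial friction builds a radial compression gradient — cells in the
colony centre are measurably smaller and taller than cells at the free
edge — and at a reproducible critical colony size the centre cells
delaminate, divisions reorient out of plane, and the tissue stratifies
into 3D. Fluid-like (unjammed) sheets such as MDCK monolayers instead
dissipate the stored elastic energy by in-plane rearrangement and keep
spreading in 2D. `morphomech` implements (i) the continuum shear-lag model
of this compression gradient with an energy-based delamination criterion,
(ii) the image-derived quantifications that test it (per-cell strain
fields, shape index, PIV, spindle angles, T1/rosette detection), (iii) a
discrete growth simulator that reproduces the solid→3D / fluid→2D
dichotomy, and (iv) synthetic-data generators with full ground truth so
every stage is testable without microscopy data.

## Shear-lag model of the compression gradient

The sheet is treated as a thin linear-elastic film of thickness $h$
(µm) and effective modulus $\bar{E}$ (Pa) on a rigid substrate. During
expansion the substrate exerts a constant interfacial shear traction $f$
(Pa) directed toward the colony centre. Radial force balance with
constant traction gives the classical shear-lag solution

$$\sigma(r) = \frac{f\,(R - r)}{h},$$

with $R$ the outer radius, $r$ the distance from the centre, and
compression counted positive: the stress vanishes at the free edge and is
maximal, $fR/h$, at the centre. We assume an equibiaxial state
($\sigma_r = \sigma_\theta$), absorb any Poisson factor into $\bar{E}$ (the
model must be identifiable from area data alone, and area data cannot
separate the two), and use the linear strain $\varepsilon = \sigma/\bar{E}$.
The observable is the cell-area profile

$$A(r) = A_0\,\bigl(1 - k\,(R - r)\bigr)^2, \qquad k = \frac{f}{h\bar{E}},$$

fitted by `fit_area_profile()` (Levenberg–Marquardt, $R$ fixed to the
frame's colony radius for identifiability, $A_0$ and $k$ free, iteration
cap 200, relative tolerance $10^{-10}$; a negative unconstrained optimum
is clipped to $k = 0$ and flagged).

Delamination — the mechanical proxy for the onset of stratification — is
predicted where the stored elastic energy per unit interface area,
$U = \sigma^2 h / (2\bar{E})$ (J/m²), reaches the interfacial adhesion
energy $\Gamma$. Solving $U(\sigma(0)) = \Gamma$ gives the critical
colony radius

$$R^* = \frac{\sqrt{2\,\bar{E}\,h\,\Gamma}}{f},$$

decreasing in $f$ and increasing in each of $\bar{E}$, $h$, $\Gamma$; with
$f = 0$ the sheet never delaminates and `critical_radius()` returns
`Inf`. Post-delamination buckling mechanics and substrate deformation are
out of scope: stratification is reported as an onset event, not a shape.

## Per-cell strain fields

Strain is computed from segmented areas with the linear convention

$$\varepsilon = 1 - \sqrt{A / A_0},$$

positive under compression, so that a cell lying exactly on the
shear-lag area profile has $\varepsilon = k(R-r) = \sigma/\bar{E}$: the
strain-field and shear-lag conventions compose exactly (this identity is
tested to $10^{-12}$). The areal alternative $1 - A/A_0$ differs only in
this composition property, which is why the linear form is the default.
The reference area $A_0$ is the mean cell area of an early frame
(`reference_area()`, configurable frame index), standing in for the
"full-grown, uncompressed" cell. The colony centroid is area-weighted,
which is robust to protrusive cells at the edge; strain maps are rendered
by nearest-cell assignment inside the colony disc and left undefined
outside.

## Tissue-fluidity metrics

The cell shape index $p_0 = \text{perimeter}/\sqrt{\text{area}}$ has an
isoperimetric floor of $2\sqrt{\pi} \approx 3.5449$ (a disc); vertex-model
theory places the jamming/unjamming transition of a confluent tissue at a
median $p_0^* \approx 3.81$. `classify_jamming()` stores this threshold as
its default and classifies the boundary value as fluid-like (a side must
be chosen; the choice is documented and configurable). Values below the
floor are reported with a data-quality warning rather than suppressed,
since they indicate segmentation problems the user should see.

PIV follows the MatPIV-class baseline: one pass, 32-px interrogation
windows at 50% overlap, mean-subtracted windows, FFT cross-correlation on
a zero-padded grid normalised by the window-overlap area (this removes
the systematic bias of the correlation peak toward zero displacement),
three-point Gaussian sub-pixel refinement per axis, a first-to-second
peak-ratio validity test at 1.2, and single-pass 3×3 local-median
replacement of invalid vectors. Displacements beyond a quarter window are
not trusted. Window deformation, multi-pass schemes and optical flow are
deliberately out of scope. The rms velocity subtracts each field's mean
vector first (drift removal) and then averages
$\sqrt{\langle |v|^2 \rangle}$ over fields; subtraction can be disabled
when the drift is known to be negligible, but subtracting is the default
procedure.

## Division orientation

The spindle-axis angle is
$\arcsin(|\hat{a} \cdot \hat{n}|)$ in degrees, with $\hat{a}$ the
pole-to-pole axis and $\hat{n}$ the substrate normal (default $+z$,
configurable for tilted cryosections); it is invariant under pole
swapping and in-plane rotation. Divisions are classified symmetric
(parallel) up to and including 30° and asymmetric above, with tripartite
labels parallel/oblique/perpendicular at 30°/60° — the conventional
binning, configurable, boundaries inclusive on the lower class. The
association between cell deformation (thickness/width) and spindle angle
is summarised by the Spearman rank correlation with mid-ranks for ties.
The "extent" of metaphase-plate oscillation is defined here as the total
absolute angular path length divided by elapsed time (deg/min); since
amplitude- or SD-based definitions also exist in the literature, the raw
path length is reported alongside and the definition is recorded in the
output.

## Cell rearrangements

T1 transitions are detected on junction-graph time series: a junction
between cells $(a,b)$ shrinking below `L_min` (default 1.0 µm) at frame
$t$ is confirmed as a T1 when a junction between the other two members
$(c,d)$ of the adjacency quad appears within a persistence window
(default 3 frames); each quad emits at most one event, kept at its
earliest confirmation (the counting rule for overlapping quads is the
package's choice, fixture-validated). The detector is symmetric under
time reversal with losing/gaining pairs swapped. Rosettes are vertices
with at least 5 incident cells (4-fold vertices are transient T1
midpoints, hence excluded by default); junction vertices are merged
within 0.25 µm, a sub-cell-scale tolerance that avoids spurious
high-order vertices from numerical jitter. The directional tissue
elongation rate fits the affine map between tracked centroid
configurations, removes the rigid rotation by polar decomposition
$F = RU$, and reports $\hat{d}\cdot\log U\,\hat{d}$ per unit time — exact
for affine motions, exactly zero for rigid ones.

## Discrete growth simulator

The finite-element plate problem is reduced to a 1D radial chain under
axisymmetry: elements of rest length $l_i$ and stiffness
$\bar{E}h/l_i$ between nodes pinned to the substrate by rate-independent
Coulomb friction of constant traction magnitude $f$ over their tributary
interface length. Constant traction is chosen deliberately: it makes the
fully mobilised discrete stress profile equal the shear-lag solution
$f(R-r)/h$ at element midpoints *exactly*, so the continuum model serves
as an exact oracle for the simulator (and vice versa); an L2 comparison
between the two therefore sits at solver tolerance rather than on a
discretisation-error curve. Growth multiplies rest lengths by
$e^{g\,dt}$ per step; fluidity enters as Maxwell stress relaxation
$\sigma \leftarrow \sigma e^{-dt/\tau}$ implemented as rest-length creep
(relaxation only lowers nodal forces, so it cannot break equilibrium);
an element delaminates irreversibly when $\sigma^2 h/(2\bar{E}) \ge
\Gamma$, and its interfacial coupling is removed. The time step obeys
$g\,dt \le 0.01$ and $dt \le \tau/10$.

Each step solves the incremental quasi-static problem, which is the
minimisation of the convex energy
$\sum_i \tfrac{k_i}{2}(L_i - l_i)^2 + \sum_j C_j |r_j - r_j^0|$
(elastic energy plus friction dissipation at constant traction, $C_j$
the nodal capacity). A primal active-set method is used: given a
stick/slip assignment, the balance is an exact tridiagonal solve (Thomas
algorithm); a line search sticks any node driven back to its
start-of-step position, and the most violated stuck node is released
with the sign of its net force. The assignment warm-starts from the
previous step, termination is finite, and Karush–Kuhn–Tucker residuals
are verified to $10^{-8}$ of the friction force scale. The solver is
deterministic; the seed only jitters the optional initial geometry.

Two regimes emerge. With $\tau = \infty$ (jammed) the centre stress grows
with $R$ along the mobilised envelope until the energy criterion fires:
the onset radius reproduces $R^*$ (within discretisation and
time-step granularity, about 1% at 200 elements). With $\tau$ small
enough that the growth–relaxation balance $\bar{E} g \tau$ stays below
the delamination stress $\sqrt{2\bar{E}\Gamma/h}$, the centre stress
saturates and the sheet never stratifies — the fluid-like, 2D-growth
regime. `phase_diagram()` tabulates this dichotomy over $(f, \Gamma,
\tau)$. The simulator does not model post-delamination buckling, nor the
accelerated in-plane spreading of a fluid sheet: Maxwell creep absorbs
growth into the reference configuration, so the fluid limit is read out
through its stress cap and absent stratification, not through its
spreading kinematics.

## Synthetic data and what passing tests mean

Every generator is a pure function of its spec and seed (the caller's
RNG state is saved and restored) and returns the full ground truth
needed to predict downstream measurements.

* `make_radial_tessellation()` draws cell positions from the number
  density $1/A(r)$ implied by the target area profile (inverse-CDF
  sampling of the same intensity a rejection scheme would target) and
  assigns each cell its on-profile area times lognormal noise of the
  requested CV, so a noiseless spec lies exactly on the profile.
  Defaults — $A_0 = 400$ µm², $R = 300$ µm, $k = 10^{-3}$/µm (centre
  strain 0.3), CV 0.1, 500 cells — represent a well-developed ~20-µm-cell
  colony with a strong gradient. Perimeters follow a regime-dependent
  shape-index profile (compressed central cells rounder; fluid tissue
  above 3.9).
* `make_growth_series()` keeps solid-like per-cell noise multipliers
  fixed (persistent areas) while $R$ grows and $k$ strengthens; the
  fluid-like variant grows 1.3× faster with $k = 0$ and per-frame
  lognormal area noise with temporal correlation 0.5 — a stand-in
  process, chosen once, not a claim about the real fluctuation dynamics.
  Cell number is fixed (no proliferation events).
* `make_speckle_pair()` advects Gaussian-filtered white noise (~2 px
  grain) by an exactly known uniform or rigid-rotation field with
  bilinear inverse mapping.
* `make_division_events()` places spindle poles at exactly the coupled
  angle; `make_t1_sequence()` scripts quad swaps (junction 2.4→1.6→0.8 µm,
  then the orthogonal junction 0.8→1.6→2.4 µm) and static $m$-fold
  rosettes in disjoint patches; `make_motion_tracks()` contrasts
  persistent random walks (rms speed $v$) with caged jitter (rms speed
  $v/5$, plateauing MSD).

These fixtures have exact polygons, no segmentation errors, no imaging
noise beyond what is injected, and scripted topology. Passing tests
therefore demonstrate the *correctness of the estimators and detectors
under their stated models*, not robustness to real microscopy artefacts
(debris, over/under-segmentation, drift in z, operator-dependent slice
selection — the manual steps of the original workflow are explicitly not
replicated).

## Problem sizes and reproducibility

The test-suite and acceptance configurations are desk-scale by design:
200–400 simulator elements, 9-point $(f,\Gamma)$ onset grids, colonies
of 500 cells, 256² speckle images with 225 interrogation windows, 50
Monte-Carlo seeds for noisy gradient recovery, and 20 scripted
rearrangement fixtures. All randomness flows from a single integer seed
per generator call; writers emit plain CSV/YAML, and identical
(config, seed, input) triples produce byte-identical outputs.

## Known limitations

* The exact algebraic forms of the original supplementary equations are
  not available; the closed-form stress profile, the linear strain
  convention and the fixed-$R$ fit are documented stand-ins consistent
  with the model's figure-level behaviour, each isolated behind one
  function and one flag.
* $\bar{E}$ is a single effective modulus; no Poisson ratio, no
  cell-level heterogeneity.
* The simulator is 1D axisymmetric with a scalar Maxwell time standing
  in for rearrangement-mediated dissipation; it reports delamination
  onset, not post-buckling shape, and its fluid-limit spreading
  kinematics are not quantitative.
* Junction graphs from polygons assume segmentations that share
  boundary vertices (vertex-model-like input); the polygon-overlap check
  assumes convex cells.
* The PIV is one-pass with a fixed window; strong shear within a window
  or displacements beyond a quarter window are outside its validated
  envelope.
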