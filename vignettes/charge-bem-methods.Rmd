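---
title: "Charge-based BEM forward modeling and dipole reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based BEM forward modeling and dipole reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chargebem)
```

## The physical model

Scalp EEG arises from cortical current dipoles conducting through head
tissues of different conductivities.  In the quasi-static regime the
potential obeys Laplace's equation within each homogeneous compartment, and
all the physics of the conductor lives on the interfaces where the
conductivity jumps.  `chargebem` uses the *charge-based* formulation of the
boundary element method: the unknown is the induced surface charge density
$\rho$ on each interface, not the double-layer potential of the classical
BEM.  Writing the total field as an impressed part $E^i$ (the source dipole
field in an infinite medium of the source compartment's conductivity) plus
the Coulomb field of the induced charges, the boundary condition (normal
current continuity) gives, at each interface point $r$,

$$
\frac{\rho(r)}{2} \;-\; K(r)\, n(r)\cdot
\int_S \frac{\rho(r')}{4\pi}\,\frac{r-r'}{\|r-r'\|^3}\,ds(r')
\;=\; K(r)\, E^i(r)\cdot n(r),
\qquad
K = \frac{\sigma_{in}-\sigma_{out}}{\sigma_{in}+\sigma_{out}},
$$

where $n$ is the outward normal and $K$ the conductivity contrast
($K = 1$ against air).  We work throughout in units of $\rho/\varepsilon_0$
(V/m), so the vacuum permittivity never appears as a number; this avoids
carrying a $10^{-12}$ scale through the solver for no physical gain.

### Discretization

Interfaces are closed triangle meshes; $\rho$ is piecewise constant per
facet and the equation is collocated at facet centroids (the facet's total
charge $\rho_n A_n$ is the summed quantity, which is also what the
refinement cost function below uses).  Three numerical choices matter:

* **Near field.**  The point-charge kernel between centroids diverges for
  adjacent facets.  For facet pairs closer than 3 local mesh lengths
  ($\sqrt{A}$), the kernel is replaced by the analytic integral of $1/r$
  (and its gradient) over the flat source triangle, computed with
  edge-term/solid-angle closed forms and validated against subdivision
  quadrature in the test suite.  The same treatment makes the surface
  potential finite *on* a facet, which is where electrodes sample it.
* **Self term.**  The $m = n$ term is excluded from the sum; the analytic
  jump term $\rho_m/2$ is the only diagonal contribution.
* **Monopole deflation.**  The continuum solution carries zero total
  charge on every closed interface (no monopole sources), but plain
  collocation leaves a discretization-level monopole defect far above
  round-off.  The solver therefore removes the area-weighted mean of
  $\rho$ on each interface from both the operator and the right-hand side
  (an oblique projection).  The deflated system is consistent, the reported
  residual is that of the deflated system, and charge neutrality holds to
  round-off after every solve.

Small systems (up to 3000 facets) are solved by dense LU; larger ones by
restarted GMRES (relative residual $10^{-6}$ by default, configurable) with
a matrix-free operator whose $O(M^2)$ direct Coulomb sum is compiled code.
The n-body backend is pluggable: the `"compiled"` backend is the default
and a pure-R `"reference"` direct sum serves as the independent check; the
two agree to near round-off, which the acceptance suite verifies on a
2000-facet instance.  A hierarchical (FMM) backend could be slotted behind
the same contract but is not part of the package.

## Head phantoms

Real-head meshes are out of scope; the synthetic-data module builds nested
icosphere phantoms instead.  The 5-layer phantom (skin, skull, CSF-boundary,
GM, WM) defaults to radii 92/86/80/78/70 mm.  The 2 mm CSF-GM gap is
deliberate: thin gaps between intracortical surfaces are the geometric
hazard that makes adaptive refinement necessary, so the default phantom
reproduces that hazard at desk scale.  The 3-layer phantom (SKIN, SKULL,
BRAIN: 92/86/80 mm) is the inverse-model analog of the decimated meshes
used by standard source-localization toolchains.  Conductivity presets
(`ITIS7`, `VWB7`, `SIMNIBS7` and their 3-layer partners) ship as an
editable text table; air outside the skin is exactly 0 S/m.  Phantom shells
may be built concentric, or with per-shell center offsets to break the
spherical symmetry.

Subdivision level 2 is the smallest that respects strict nesting across the
2 mm gap (the chord sagitta of a level-1 icosphere at 80 mm is ~2.8 mm),
which is why tests build phantoms at level 2 or finer.

## The analytic oracle

Because concentric-sphere conductors admit a semi-analytic solution, the
package carries an independent N-shell Legendre-series oracle
(`sphere_potential`).  The dipole may sit in *any* conducting region, not
just the innermost ball — necessary here because the study's sources live
in the GM shell.  Per spherical-harmonic degree, a small linear system in
scaled radial powers (all matrix entries are ratios $\le 1$, so no overflow
at high degree) couples the per-region expansion coefficients through
potential and current continuity, with the dipole's primary expansion
entering the source region's conditions.  The radial and tangential parts
of an arbitrary moment are handled by the $P_n$ and $P_n^1$ terms of a
dipole-aligned frame.  The series is truncated at degree 200 by default
(400 for sources at eccentricity near 0.95) with an early stop once terms
fall below $10^{-10}$ of the partial sum; its correctness is pinned by the
closed-form central-dipole solution, the textbook eccentric-dipole image
series, degenerate shell merging, and truncation-doubling stability.

Forward accuracy is quantified by the standard pair RDM (shape error,
$\|\hat V_{test} - \hat V_{ref}\|_2$ on normalized vectors) and MAG
(magnitude ratio).

## Adaptive mesh refinement

The AMR loop ranks facets by the cost $C_m = |\rho_m| A_m$ (total charge
magnitude), subdivides the top 1% of refinable facets — pooled across all
interfaces except the skin, which is the observation surface and is never
refined — into four midpoint-congruent children, and re-solves, warm-started
by child-inherits-parent prolongation.  Hanging nodes are allowed: facet
collocation does not require mesh conformity.  The loop stops when the
relative change of the electrode-voltage vector between consecutive steps
falls below 1% (2-norm), or after `max_steps = 15` refinements.  The first
ratio compares the first refined solve against the un-refined one, so at
least one refinement always happens.  Costs are recomputed from the fully
re-converged solution at each step.

At the phantom's default study resolution (subdivision 3, 6400 facets) the
loop reaches the 1% criterion in roughly 6–10 steps and reduces the
oracle RDM of the thin-gap phantom by an order of magnitude; at one level
coarser the voltage sequence does not settle within 15 steps, which is the
practical floor for the base resolution.

## Electrodes

Phantoms have no anatomical landmarks, so the semi-manual montage of
real-head studies is replaced by a deterministic Fibonacci cap layout:
`n = 256` near-uniform directions on the upper cap covering 65% of the
sphere (sparing the face/neck analog).  Each direction is ray-projected
onto the skin mesh and the electrode is assigned to the hit facet; its
voltage is the total surface potential at that facet's centroid.  The
voltage reference is infinity by default, with average reference available
(and exactly zero-sum).

## Source reconstruction

The inverse model is always the 3-layer phantom solved *without* AMR,
matching how standard dipole-fitting toolboxes operate.  Because the
operator of a fixed 3-layer model does not depend on the source, it is
assembled and LU-factorized once (`lead_field_context`); a lead field at
any position then costs three back-substitutions, which makes grid searches
and simplex iterations cheap.  The fit machinery is classic:

* `fit_moment`: linear least squares for the moment at fixed position (QR),
  with residual variance $RV = \|V - Lq\|^2 / \|V\|^2$;
* `grid_search`: Cartesian lattice (5 mm default) anchored at integer
  multiples of the spacing, clipped to the skull interior (and to the BRAIN
  region, where lead fields are defined), ties broken lexicographically;
* `nonlinear_fit`: Nelder-Mead over position with the nested linear moment
  fit, positions escaping BRAIN penalized with $RV = 2$; a full-scale pass
  (relative tolerance $10^{-9}$) followed by a 0.1 mm-simplex restart.
* `fit_dipole`: the user-facing front end; runs the truth-seeded and/or
  grid-seeded strategy and reports the fit with the smaller residual
  variance, as a classed object with `print`, `summary`, `coef`, `predict`
  and `residuals` methods.

Angles between true and fitted moments are reported unfolded (0–180
degrees); no antiparallel folding is applied.

## The comparison study

`run_study` reproduces the design of the underlying accuracy question at
phantom scale: simulate EEG on the 5-layer phantom (with AMR and without),
fit with the matched 3-layer phantom (`ITIS7` pairs with `ITIS3`, etc.),
and tabulate distance/angle errors per dipole and condition.  "Subjects"
are emulated as seeded phantom variants: a common radius jitter (up to 2%)
plus small per-shell jitter, and a rigid offset (up to 3 mm) of the
intracranial block (CSF/GM/WM) relative to skin and skull, halved
deterministically until strict nesting holds.  The 3-layer variant shares
the (jittered) outer radii and the offset of its BRAIN surface with the
5-layer phantom it inverts, since both descend from the same geometry.

The four canonical dipoles contrast depth and orientation:
dip1 (shallow-tangential) and dip2 (shallow-radial) sit near the GM
surface (`depth_fraction = 0.8`) under the densely covered cap pole, dip3
(mid-depth radial) sits mid-cortically at mid-latitude, and dip4 — the
deep source — sits near the WM surface (`depth_fraction = 0.12`, the
smallest radius) on a direction facing away from the electrode cap, the
way a medio-temporal source sits far from a scalp montage.  A concentric
phantom can express depth both radially (through `depth_fraction`) and
angularly (distance from the cap); the deep placement uses both, since
the real-head contrast it stands in for involves both.

Default study sizes are chosen for desk-scale runs: forward phantoms at
subdivision 3 with the WM shell one level coarser (5440 facets total; the
WM interface carries the smallest contrast, $K \approx -0.09$, and is
eligible for AMR wherever the solution demands more resolution), inverse
phantoms at subdivision 2 (960 facets), 256 electrodes, GMRES tolerance
$10^{-5}$ for study solves (the stopping observable is a 1% voltage
change, so tighter residuals buy nothing), and a 400-evaluation budget for
each Nelder-Mead fit (fits typically converge near 230 evaluations).  A
full 5-variant study takes on the order of an hour; the 2-variant smoke
version used by the acceptance suite runs in about a quarter of that.

## What the phantom study does and does not show

Passing tests demonstrate that the solver stack is internally consistent
(backends agree, conservation holds, determinism holds), converges to the
analytic solution under refinement, and that AMR materially improves both
forward accuracy (oracle RDM) and downstream localization on thin-gap
geometry.  The phantom study preserves the *structure* of a real-head
accuracy study — model-complexity mismatch (5- vs 3-layer), conductivity
sets, AMR on/off, depth and orientation contrasts — but none of its
anatomy: no cortical folding, no skull thickness variation, no
white-matter anisotropy, and noiseless single-sample EEG only.  Absolute
millimeter or degree numbers from the phantom are therefore not
comparable to real-head results; orderings (AMR better than no AMR, deep
worse than shallow) are the meaningful outputs.

## Known limitations

* Collocation with piecewise-constant charges is low-order; very thin
  gaps need AMR rather than raising approximation order (p-refinement is
  out of scope).
* The non-conforming refinement leaves T-junctions; collocation tolerates
  them, but a Galerkin discretization would not without constraint
  handling.
* The inverse model reuses the package's charge-based solver; a
  potential-based BEM (as used by common toolboxes) would add a small
  formulation discrepancy on top of the model-complexity difference
  studied here.  Implementing one is a non-goal.
* The oracle requires concentric spheres; offset-shell variants are
  validated only through the BEM's internal invariants.
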