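---
title: "Modeling biomechanics and adaptation of a resistance artery segment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling biomechanics and adaptation of a resistance artery segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseladapt)
```

## The system being modeled

Small arteries and arterioles set peripheral resistance. They are not passive
tubes: their diameter is regulated acutely by smooth muscle cell (SMC) tone
and chronically by structural adaptation. `vesseladapt` implements a single
arterial segment under constant or stepwise pressure `P`, flow `Q`, and two
lumped vasoactive inputs — an extrinsic constrictor `CON`, expressed as the
wall stress that would produce an equipotent myogenic stimulus, and an
extrinsic dilator `DIL`, expressed as an equipotent shear stress. The state
of the wall is five-dimensional:

* `eps` — strain of the extracellular matrix, the relative extension of the
  midwall radius over its slack (unloaded) value;
* `tone` — SMC activation between 0 (fully relaxed) and 1 (fully active),
  defined as the ratio of actual to maximal active stress at the same cell
  length;
* `span` — the fraction of the circumference covered by one SMC, so that
  cell length is `l = span * 2 * pi * r_m`;
* `r_mslack` — the slack midwall radius of the matrix;
* `wcsa` — the wall cross-sectional area.

Any two of internal radius, midwall radius, thickness and wCSA fix the
geometry. The package uses the exact circular-annulus convention
`wcsa = 2 * pi * r_m * h` with `r_i = r_m - h/2`; the thin-wall Laplace
relation `sigma_eq = P * r_i / h` then closes the mechanical balance.

## Wall mechanics

Three stress-bearing elements lie in parallel, each covering one third of
the wall cross-section by default, so the mean wall stress is the
area-fraction-weighted sum of the element stresses.

* **Passive matrix** (`matrix_stress`): a bi-exponential stress–strain law,
  `c_p1*(exp(c_p3*eps)-1) + c_p2*(exp(c_p4*eps)-1)`, zero for slack matrix
  (`eps <= 0`). The first term carries moderate strain; the second is
  negligible until high distension and then dominates steeply, reproducing
  the strain-stiffening of fibrous matrix.
* **Active SMC stress** (`active_stress_capacity` times tone): capacity is a
  Gaussian bell of cell length centered on the optimum `l_opt = 106.18` µm
  with width `l_w = 45.868` µm and peak `sigma_amax = 250` kPa. Working with
  cell length rather than radius is what allows SMC rearrangement to move
  the active length–tension relation along the radius axis.
* **Cytoskeletal brake** (`cytoskeletal_stress`): a steep exponential in
  cell length anchored at 250 kPa at `c_c3 = 118.92` µm. It is below 1% of
  its anchor value at the reference length and prevents stretch of the cell
  much beyond the anchor. The tabulated steepness (30) is treated as
  dimensionless in `exp(c_c2 * (l - c_c3)/c_c3)`; the commonly quoted unit
  of m^-1 for this constant is not dimensionally consistent with a brake of
  this form, and the anchored exponential is the natural unit-consistent
  reading.

Wall shear stress is Poiseuille, `tau = 4*eta*Q/(pi*r_i^3)`, with constant
blood viscosity.

## The five rate processes

All regulation is first-order. With the variant mask gating each term:

1. **Mechanics** — strain relaxes toward the Laplace equilibrium,
   `deps/dt = k_mech*(sigma_eq - sigma)`. This is the fastest process
   (seconds to minutes) and is active in every variant.
2. **Tone** — activation tracks its set point, `dA/dt = k_tone*(A_eq - A)`.
   The set point multiplies a myogenic Hill function of wall stress plus
   constrictor (half-activation 30 kPa, coefficient 3) by a tone-reducing
   factor `TRF = 1 - ecf * Hill(tau + DIL)` (half-maximal at 5 Pa shear,
   coefficient 3). `ecf` scales endothelium-mediated dilation; 0 abolishes
   it.
3. **SMC plasticity** — span adapts so cell length returns to the reference
   `l_ref = 80` µm:
   `dspan/dt = k_span * span * (l/l_ref) * (l_ref - l)`. The extra factor
   `l/l_ref` makes the relative rate of length change proportional to the
   ratio of actual and reference length, a geometric consequence of cells
   repositioning along the circumference.
4. **Eutrophic remodeling** — the slack radius follows the balance of
   strain-driven outward and tone-driven inward rearrangement of existing
   matrix, `dr_mslack/dt = k_slack * r_mslack * (beta_strain*eps -
   alpha_tone*A)`; proportionality to `r_mslack` keeps the law geometric
   (relative caliber change). With the defaults (`alpha_tone = 0.65`,
   `beta_strain = 1`) the balance point couples steady-state strain to tone.
5. **Growth** — wall mass follows wall stress,
   `dwcsa/dt = k_growth * wcsa * (sigma - sigma_ref)`, with the reference
   stress `sigma_ref = 30` kPa. Composition fractions are preserved during
   growth.

The rate constants span five orders of magnitude (mechanics ~10 s, tone
~200 s, plasticity ~1 h, remodeling ~day, growth ~days–weeks), which makes
the system stiff; this ordering is itself asserted by a test.

At any stable fixed point of the full model the five laws force the
identities `sigma = sigma_ref`, `l = l_ref`, `A = A_eq`,
`sigma = P*r_i/h` and `beta_strain*eps = alpha_tone*A`. Everything else —
radius, wall mass, slack radius, shear — follows algebraically. This is why
the model predicts perfect pressure homeostasis of the radius and perfect
shear regulation against flow, and why shear plus dilator stimulus is
conserved across dilator levels up to the point where the required shear
would be negative: beyond it no fixed point exists and the radius runs away.

## Model variants

`vessel_variant()` encodes the hierarchy MECH (mechanics only), FUNCT
(+tone), PLAST (+plasticity), REMOD (+remodeling), GROWTH (all five), and
the single-process knockouts FUNCTKO, PLASTKO, REMODKO. A disabled process
contributes exactly zero rate and its state component stays frozen — by
convention at the full-model steady state under default conditions
(P = 80 mmHg, Q = 0.25 µL/s, no agents).

## Numerical design

* **Integration**: `deSolve::lsodar` (variable-step, stiff-capable), with
  relative tolerance 1e-5 and absolute tolerances 1e-5 (strain), 0.001
  (tone, span), 0.01 µm (slack radius), 1 µm² (wCSA). Integration restarts
  at protocol breakpoints. Root functions terminate a run when the internal
  radius leaves the guard band (default 1% to 20x its initial value),
  yielding collapse/runaway verdicts; the guards are wide enough never to
  trigger on ordinary step-response transients.
* **Strain floor**: compressed matrix buckles, so stresses are floored at
  zero for `eps <= 0` and the strain itself is floored at -0.5. Compressive
  strain rates ramp linearly to zero over the last 0.01 strain units above
  the floor, making the clamped state an ordinary equilibrium rather than a
  discontinuity that a stiff solver chatters on.
* **Steady states** (`vessel_steady_state`): integrate to t = 1e8 s
  (~3 years, several hundred times the trophic time scale), then polish
  with a damped Newton iteration on the masked rate vector, using central
  finite-difference Jacobians in tolerance-scaled coordinates. A state is
  declared stable only if the scaled residual `max |rate_i|/atol_i` falls
  below 1e-10. Integrate-then-polish is deliberate: the system has unstable
  fixed points (all knockouts of tone regulation), and integration selects
  the attractor a vessel would actually reach before the root-finder
  sharpens it to machine precision.
* **Initial states**: searches start from the default working point with
  the active components displaced by 10%. Starting exactly on a fixed point
  would mask instability (a saddle looks converged); starting too far away
  would leave the physiological basin at extreme inputs. The displacement
  value is immaterial within a wide range — the basin at default conditions
  covers half-to-double per admissible component, which is tested.
* **Basin limits**: robustness to displaced initial conditions holds up to
  geometric feasibility. A start whose acute mechanical equilibrium (at its
  initial tone and structure) already closes the lumen — e.g. wall area
  doubled at fixed slack radius — collapses on the mechanical time scale,
  before tone or structure can respond. This is a property of the model,
  not of the solver, and the tests assert the collapse rather than hide it.
* **Quasi-static curves**: pressure–radius relations at pinned tone are
  computed by root continuation of the scalar mechanical balance from the
  working point outward, which follows the physical branch where the fully
  activated balance is S-shaped. Where no open-lumen root exists the state
  rests at the strain floor (a fully constricted, near-closed vessel).
* **Sensitivities** (`sensitivity_matrix`): central differences with ±5%
  parameter perturbation by default. A ±50% mode mirrors half-to-double
  variation studies; entries whose perturbed model has no stable steady
  state are reported as NA rather than extrapolated.

## Problem sizes used in the tests

The test suite solves a few dozen steady states (each a fraction of a
second), one 9 x 4 sensitivity matrix, pressure–radius curves on a 25-point
grid, two step responses on 400-point log-time grids, a reduced
steady-state map (two variants, 2–3 values per input) and a dilator scan
with 0.5 Pa spacing. These sizes were chosen as the smallest grids on which
each scientific property is distinguishable from its failure mode; all
results are deterministic, so no replication is needed.

## What the simulator does and does not capture

The segment is driven by constant or piecewise-constant inputs: there is no
feedback from the perfused tissue (which would make `CON`/`DIL` depend on
supply and demand) and no network, so pressure and flow never respond to
the vessel's own conductance. Elastin and collagen are lumped into one
matrix element; growth preserves composition and material properties;
vasoactive agents act only through tone, not directly on remodeling or
growth; SMC are perpendicular to the axis (zero pitch) and axial mechanics
are ignored. Passing tests therefore demonstrate the internal consistency
and regulatory logic of the single-segment model — regulated wall and shear
stress, matched active/passive biomechanics, preserved dilatory reserve —
not quantitative prediction for any particular vascular bed.

## Worked example

```{r example, eval = FALSE}
ss <- vessel_steady_state()          # full model, 80 mmHg, 0.25 uL/s
ss

S <- sensitivity_matrix()            # 9 outputs x 4 parameters, +-5%
round(S[c("r_i", "tone", "tau"), ], 3)

scan <- dilator_scan()               # conserved tau + DIL, runaway beyond
scan
```
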