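# vesseladapt

Integrative simulation of resistance-artery biomechanics and adaptation.

Small arteries and arterioles regulate organ perfusion, and their
dysregulation — eutrophic inward remodeling, hypertrophy, loss of dilatory
reserve — is central to hypertension and other cardiovascular disease. The
diameter of such a vessel is controlled by processes spanning five orders of
magnitude in time: acute mechanics, smooth muscle tone, repositioning of
smooth muscle cells, rearrangement of the existing matrix, and growth of
wall mass. Because these processes share stimuli and feed back on each
other, their combined behavior is hard to reason about verbally; this
package implements them as one coherent dynamical system for researchers in
vascular physiology and cardiovascular modeling.

## The model

A single arterial segment under pressure *P*, flow *Q* and lumped
vasoactive agents (*CON*, *DIL*, as equipotent wall stress and shear
stress) has state **x** = (ε, A, sp, r_mslack, wCSA): matrix strain, tone,
SMC span, slack midwall radius, wall cross-sectional area. Three parallel
elements carry the mean wall stress

σ = af_p·σ_p(ε) + af_a·A·σ_acap(l) + af_c·σ_c(l),  l = sp·2π·r_m,

with a bi-exponential passive matrix law, a Gaussian active-stress capacity
peaking at the optimal cell length, and a steep cytoskeletal stretch brake.
Loading follows Laplace (σ_eq = P·r_i/h) and Poiseuille shear
(τ = 4ηQ/(πr_i³)). Five first-order rate laws drive the state:

- dε/dt = k_mech·(σ_eq − σ)
- dA/dt = k_tone·(A_eq − A), A_eq = Hill(σ + CON)·[1 − ecf·Hill(τ + DIL)]
- dsp/dt = k_span·sp·(l/l_ref)·(l_ref − l)
- dr_mslack/dt = k_slack·r_mslack·(β·ε − α·A)
- dwCSA/dt = k_growth·wCSA·(σ − σ_ref)

Model variants (MECH, FUNCT, PLAST, REMOD, GROWTH) switch these processes
on cumulatively; software knockouts (FUNCTKO, PLASTKO, REMODKO) remove one
process from the full model. The package provides stiff integration with
collapse/runaway guards, steady-state solving with root polishing,
pressure–radius curves, step-response and steady-state-map protocols, a
parameter sensitivity matrix, a dilator-instability scan, YAML
configuration, CSV/JSON writers and a command-line interface
(`inst/cli/vesseladapt`).

## Worked example

```r
library(vesseladapt)

ss <- vessel_steady_state()   # full model at 80 mmHg, 0.25 uL/s
ss
#> vessel_steady (GROWTH): verdict stable
#>   inputs: P = 80 mmHg, Q = 0.25 uL/s, CON = 0 Pa, DIL = 0 Pa
#>   r_i = 67.886 um  tone = 0.3673  l = 80.000 um
#>   r_islack = 49.595 um  wCSA = 1.212e-08 m^2
#>   sigma = 30000.0 Pa  tau = 35.611 dyn/cm2
#>   radius reserve = 1.4172  tension match = 0.9952
```

The converged vessel sits exactly on the regulatory set points: mean wall
stress equals the growth reference (30 kPa), cell length equals the
plasticity reference (80 µm), tone is intermediate (0.37) so the vessel
retains a 1.42-fold dilatory reserve, and active and passive biomechanics
are matched (tension match ≈ 1). Because those set points pin the state,
steady-state radius is independent of pressure and shear stress independent
of flow.

```r
S <- sensitivity_matrix()     # +-5% central differences around defaults
round(S[c("r_i", "tone", "tau"), ], 3)
#>         ecf  l_ref beta_strain sigma_ref
#> r_i   0.151 -0.603       0.125    -0.234
#> tone  0.000 -1.402       0.299     0.952
#> tau  -0.455  1.777      -0.375     0.696

dilator_scan()
#> Dilator scan: 21 levels; 14 stable
#>   tau + DIL over stable range: 35.61 dyn/cm2 (range 35.61 - 35.61 )
#>   largest stable DIL: 32.5 dyn/cm2
```

The sensitivity matrix shows which parameters the regulated state actually
depends on — the SMC reference length is the strongest lever on radius and
tone, endothelial function changes radius and shear but leaves tone and
reserve untouched. The dilator scan shows the conservation law: steady-state
shear falls one-for-one as the dilator rises, keeping the total dilatory
stimulus constant at about 35.6 dyn/cm², and above that level the radius
runs away (an aneurysm-like instability).

## Documentation

The methods vignette (`vignettes/vessel-adaptation.Rmd`) describes the
constitutive laws, the rate processes and their time scales, the numerical
design (tolerances, strain floor, guards, integrate-then-polish steady
states) and the model's scope and limitations.
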