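---
title: "Methods: disc swelling, ligament and posture-load models in cervdisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disc swelling, ligament and posture-load models in cervdisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervdisc)
```

`cervdisc` asks a narrow question: when the axial load on a cervical
intervertebral disc changes — in particular, when it largely disappears in
microgravity — what happens to the disc's height, volume and water content,
to the cervical ligaments stretched by the swelling spine, and to the
per-level force pattern? This vignette documents the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## The Donnan swelling model

A disc is treated as a lumped cylinder of reference height $h_0$ and face
area $A_0$, split into a nucleus pulposus (NP) core and an annulus fibrosus
(AF) ring. The tissue is a charged hydrated matrix: glycosaminoglycans carry
a fixed charge density (FCD) $c_0^F$ referenced to the water volume at
reference geometry, where the water fraction is $\phi_0$.

Deformation is parameterised by the height ratio $r = h/h_0$, and $r^3$ is
used as the tissue volume ratio. Two conservation statements follow. The
solid matrix volume $(1-\phi_0)$ is constant, so the deformed water fraction
is
$$\phi(r) = \frac{\phi_0 + r^3 - 1}{r^3},$$
and the bound charge is constant, so the FCD dilutes as
$$c^F(r) = \frac{c_0^F\,\phi_0}{\phi_0 + r^3 - 1}.$$
Both require $r^3 > 1-\phi_0$ (positive deformed water volume); the code
raises a domain error, naming the bound, otherwise.

The swelling pressure is the ideal Donnan osmotic pressure against an
external 1:1 salt bath at concentration $c^*$:
$$F_s(r) = R\,T\left(\sqrt{c^F(r)^2 + 4c^{*2}} - 2c^*\right),$$
which is zero at $c^F = 0$, strictly increasing in $c^F$, and asymptotically
$R\,T\,c^F$ for $c^F \gg c^*$. Activity and osmotic coefficients are taken
as 1 (no non-ideal corrections), and the model is equilibrium-only: no
poroelastic creep, no permeability, no time constant.

The NP and AF share a single height ratio — the disc moves between rigid
endplates — but keep their own reference water fractions and FCDs. The disc
pressure is the area-weighted sum of the compartment pressures, and the
combined water fraction mixes by the same weights,
$\phi = f_{NP}\,\phi_{NP} + (1-f_{NP})\,\phi_{AF}$. Because $\phi(r)$ is
affine in $\phi_0$ at fixed $r$, the mixture is exactly the update applied
to the mixed reference fraction; the suite asserts this identity to 1e-12.

### Equilibrium

Mechanical equilibrium under an axial force $F$ is
$$F_s(r)\,A_0 = F.$$
$F_s$ is strictly decreasing in $r$ (dilution lowers pressure), so the root
is unique. It is found by bisection — chosen over derivative-based methods
for guaranteed convergence on a monotone residual — with a relative
tolerance of 1e-10 on $r$ (configurable) and a hard iteration cap of 200.
The bracket starts at the domain edge $r_{\min} = (1-\phi_{0,AF})^{1/3}$
(nudged inward by a relative 1e-9, where the pressure is finite but
enormous) and expands upward by doubling until the residual changes sign.
Two edge cases are handled explicitly: a force above the attainable pressure
range raises a bracketing error reporting that range, and $F = 0$ has no
finite root — pressure only vanishes asymptotically — so the solver reports
$r = \infty$ with zero residual rather than fabricating a large number.

Two open choices were settled as follows:

* **Load-bearing area.** The balance uses the reference area $A_0$, not a
  deformed area. The packaged per-scenario areas do not follow any single
  $h$-scaling law (they grow 3–7 % while heights grow 1–5 %), so deformed
  area is kept as independent data rather than entering the balance; a
  config switch `solver$area_mode = "deformed"` (scaling the face by $r^2$)
  exists for sensitivity analysis.
* **NP reference FCD.** No consensus measured value exists for
  $c_{0,NP}^F$ in the cervical disc; the default is 250 mol/m³, a typical
  healthy-disc magnitude, exposed as `disc$c0F_NP_mM` and recoverable from
  data with `recover_c0F()`.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `R` | 8.3144 | J K⁻¹ mol⁻¹ | gas constant |
| `T_kelvin` | 310.15 | K | body temperature |
| `c_star` | 150 | mol/m³ | external Na⁺/Cl⁻ bath |
| `phi0_np`, `phi0_af` | 0.80, 0.75 | — | reference water fractions (all levels) |
| `np_area_fraction` | 0.40 | — | NP share of the disc face |
| `fcd_ratio_af_np` | 0.80 | — | AF FCD relative to NP |
| `c0F_np` | 250 | mol/m³ | NP reference FCD (calibratable) |
| `solver$tol` | 1e-10 | — | relative bisection tolerance on r |

Interfaces use mm, mm², mm³, kPa, N and mol/m³ because every packaged table
does; conversions (Pa→kPa, kPa·mm²→N) happen exactly once, at the formula
boundary.

## Ligament model

The anterior and posterior longitudinal ligaments and the ligamentum flavum
are piecewise-linear springs. The packaged stiffness table carries one
segment per ligament per cervical region (C2–C5 and C5–T1) — the two rows
per ligament in the cadaveric source are read as region-specific, since
their strain ranges overlap and a single-ligament multi-segment reading
would be ill-formed. One printed strain range (LF, caudal region) arrives
reversed and is normalised to ascending order, noted in the fixture.

Force at strain $\varepsilon$ (%) is $k(\varepsilon)\,\delta$ with
elongation $\delta = \max(0, (\varepsilon - \varepsilon_{slack})/100 \cdot
L_0)$. The stiffness profile is constant below the first segment and above
the last, and interpolates linearly across gaps, keeping force continuous;
with the packaged single-segment regions it reduces to a linear spring per
region. Two constants have no measured source and are explicit modelling
defaults: the reference length $L_0$ (20 mm per region) and the slack
strain (0 %). Consequently per-ligament force totals are treated as
*calibration* targets — `calibrate_ligament_strains()` inverts totals into
regional strains that `total_ligament_force()` round-trips — never as
forward predictions. A report annotation compares totals against cadaveric
failure thresholds (ALL 494 N, PLL 462.9 N, LF 315.8 N).

## Quasi-static posture loads

Full inverse dynamics with muscle recruitment is the province of dedicated
musculoskeletal engines and is deliberately not replicated; the packaged
per-scenario load tables stand in for such output. For forward experiments
the package provides a transparent approximation: per level, the supported
weight (head mass 6.94 % of a 72 kg body, ~0.23 kg per cervical segment,
scaled by the scenario's gravity factor) is resolved through the level's
sagittal tilt into compression $W\cos\theta$ and shear $-W\sin\theta$
(positive shear points posterior, so an anteriorly tilted disc under gravity
sees anterior, negative shear). A lumped extensor balancing the
gravitational flexion moment (lever arm growing 60→140 mm cranio-caudally,
extensor moment arm 35 mm) adds compression, and a constant co-contraction
offset (default 30 N) keeps compression nonzero at 0 g — in weightlessness
the residual 20–45 N disc loads come from muscle tone and ligament tension,
not gravity, and the offset is a declared tuning constant standing in for
that mechanism, not a prediction. Default per-level tilts rise linearly from
6° (C2C3) to 10° (C7T1); a scenario may override them per level, and a
whole-neck flexion angle (24° for the floating posture) shifts all tilts.
The properties the suite asserts — linearity in the gravity factor,
magnitude preservation when muscle terms are off, sign conventions,
cranio-caudal compression ordering — are exactly the properties the design
guarantees; absolute agreement with a recruitment-optimising engine is not
claimed anywhere.

## Report reproduction and known inconsistencies

The reporting stage has two modes. *Paper mode* (default) reads the
packaged per-scenario load/state/ligament tables and recomputes every
contrast cell: relative change in percent (rounded half away from zero to
one decimal, the convention of the packaged tables; raw values are always
retained alongside), force differences in N, and ratio-style percentages
(percent change + 100) where the source tables used that convention.
*Forward mode* chains the posture loader into the swelling solver and is
labelled experimental in the bundle metadata.

Of the 134 tabulated contrast cells, 113 reproduce exactly at printed
precision. The 21 that do not are carried verbatim with flags and both
numbers side by side — never silently corrected (`known_discrepancies()`
lists them): one scenario volume inconsistent with its own height × area
(and the one derived cell that only matches the corrected volume), the 18
geometry cells of one contrast that are not derivable from the per-scenario
tables under any convention tried, and two cells that sit on or across a
rounding boundary (an exact 6.25 tie printed as 6.2; a 3.95 printed as 3.9).
The per-level water contents of the 1 g scenario (NP 80–83 %) cannot be
derived from the single shared reference fraction of 0.80 plus the swelling
equations — their provenance is unstated — so state tables store scenario
values verbatim rather than deriving them, and `recover_c0F()` exists to
quantify, per level, what FCD a given (load, water content) pair implies.

## Synthetic data and what the tests show

The generators emulate the study's input classes so every stage is testable
without external data: disc parameter populations (independent lognormal
perturbations of A0 and h0 with configurable CV — lognormal to preserve
positivity; default CV 5 %, a realistic inter-subject geometric spread),
random admissible postures, uniform axial loads on 10–200 N (spanning the
observed 0 g and 1 g disc loads), and water-content observations with
additive Gaussian noise (default sd 0.005 on the fraction scale, i.e. half
a percentage point, the precision at which such fractions are tabulated);
draws outside (0,1) are resampled, not clipped, to avoid boundary point
masses. All draws run under a single integer-seeded stream and restore the
caller's RNG state.

Parameter recovery closes the loop: generate loads at a known
$c_{0,NP}^F$, solve to equilibrium, observe water fractions, and refit the
FCD by least squares over a bracketed scalar search (Brent's `optimize`
around the bisection solver). Noiseless data recover 250 mol/m³ to well
below 0.1 %; at noise sd 0.005 with 50 observations the relative RMSE over
100 seeded replicates is about 0.3 %. The equilibrium solver is also checked
against a brute-force grid scan (10⁶ points over the admissible height-ratio
range, an independent re-implementation of the pressure formulas) on 100
randomized parameter sets.

These tests validate *internal consistency*: the solver inverts the model,
the generators realise their nominal moments, the report reproduces its
source tables. They do not validate the model against living tissue — the
synthetic data contain no measurement bias, no per-level FCD heterogeneity,
no viscoelastic transients, and no posture-dependent muscle recruitment, so
passing says nothing about those aspects of real discs.

Problem sizes throughout (10⁶-point oracle grids, 100-replicate Monte Carlo,
1000-subject CV checks) were chosen so the full suite and the acceptance
script each run in well under a minute on a laptop while leaving the
statistical checks comfortably powered.

## Limitations

* Equilibrium-only swelling: no creep, no diurnal or in-flight time course.
* Ideal Donnan activity; no osmotic coefficients.
* One height ratio per disc; no bulging geometry, no finite-element detail.
* Ligament $L_0$ and slack are defaults, so ligament forces are calibrated,
  not predicted.
* The posture loader is a sagittal-plane, quasi-static stand-in; Table-style
  per-muscle forces are out of scope (in the weightless scenarios they are
  optimizer residue of order 10⁻⁵ N).
* Single male anthropometry (72 kg, 1.74 m) by default; configurable but
  not validated across body types.
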