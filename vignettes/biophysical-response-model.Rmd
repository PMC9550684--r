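---
title: "A desk-scale biophysical model of neoadjuvant tumor response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale biophysical model of neoadjuvant tumor response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tumorsim)
```

## The model

`tumorsim` simulates how a breast tumor responds to neoadjuvant
chemotherapy, voxel by voxel, and converts the simulated residual volume at
surgery into a binary prediction of pathologic complete response (pCR). It
couples five mechanistic layers on a cubic lattice:

1. **Perfusion.** Each voxel carries extended Tofts parameters
   (`Ktrans` in 1/min, `ve`, `vp`). The tissue concentration of any
   blood-borne species follows
   $C_t(t) = v_p C_p(t) + K^{trans}\int_0^t C_p(\tau)\,
   e^{-(K^{trans}/v_e)(t-\tau)}\,d\tau$, and the same
   `Ktrans`/`ve` map fitted from (synthetic) DCE concentration series is
   reused as the delivery field for nutrients and drugs, scaled per species
   by a relative-permeability factor (default 1; 0.1 for antibodies). This
   contrast-agent-to-drug analogy is a modeling choice: nothing in the
   perfusion fit constrains drug extravasation directly. Vessel-labeled
   voxels act as Dirichlet sources clamped at the plasma concentration — a
   deliberately simple reading of a "macrovascular" compartment.

2. **Transport.** Every species obeys an explicit reaction–diffusion
   equation (forward-time, 6-neighbor centered-space stencil, zero-flux
   boundaries), substepped to the 3D stability bound $\Delta t \le h^2/6D$.
   The mirror-boundary stencil conserves mass exactly in closed domains;
   negativity produced by sinks is clipped and logged, and a run aborts if
   a step clips more than a configurable fraction of a field's mass.

3. **Metabolism and growth.** A reduced two-nutrient Monod model stands in
   for genome-scale metabolism:
   $\mu = \mu_{max}\frac{G}{G+K_G}\frac{O}{O+K_O}$, uptake proportional to
   the local cell density, and lactate produced from glucose at yield
   $Y_L \le 2$ weighted by the hypoxia factor $K_O/(O+K_O)$. Amino acids
   are tracked conceptually but non-limiting: no kinetics for them are
   established at this scale. Cell density follows a logistic-limited
   update $\rho' = \rho + \Delta t\,(\mu(1-\rho/\rho_{max}) - \delta)\rho$,
   clamped to $[0, \rho_{max}]$.

4. **Pharmacokinetics / pharmacodynamics.** Plasma drug concentration is
   the superposition of bolus responses (1- or 2-compartment), honoring
   documented dose reductions; tissue levels come from the perfusion layer;
   the specific kill rate is the Hill law
   $\delta = k_{max} C^h/(C^h + IC_{50}^h)$, combined additively across
   concurrent drugs (independent action; a "max" rule is available).
   HER2-directed antibodies additionally suppress growth through a
   growth-multiplier that engages with the same Hill saturation.

5. **Mechanics.** A mass-spring mesh (springs on lattice edges plus face
   diagonals at half stiffness) converts net growth into deformation: each
   cell's preferred volume scales by $g = e^{(\mu-\delta)\Delta t}$, rest
   lengths by $g^{1/3}$, and damped relaxation (with energy backtracking,
   so the spring energy never increases) finds the new shape. Density is
   remapped conservatively — cell *counts*, not densities, are preserved
   under volume change.

The decision rule is fixed and predefined: predicted pCR iff the residual
detectable volume at surgery is strictly below 0.01 cm³, or the volume
reduction is at least 99.9% (inclusive). Both boundaries are verified at
exact equality in the test suite.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `voxel_side` | 2.0 (0.5 supported) | mm | desk-scale resolution; all algorithms are resolution-parameterized |
| `dt_outer_h` | 6 | h | outer coupling step; transport substeps internally |
| `rho_detect` | 0.10 | — | imaging-equivalent detection threshold: volume counts voxels above `rho_detect * rho_max`, mirroring comparison against MRI segmentations rather than total cell mass |
| `mu_max` | 0.002 | 1/h | unconstrained-growth doubling ~2 weeks, an aggressive neoadjuvant-scale tumor |
| `K_G`, `K_O` | 1.0, 0.01 | mM | literature-order Monod half-saturations |
| `kill_max` | 0.0015–0.004 | 1/h | per-drug; sized so a standard regimen at unit sensitivity is *marginal* for pCR, letting per-case sensitivity multipliers generate both outcomes |
| AIF | biexponential, Weinmann-type constants | mM, 1/min | population default, literature-derived |

Every drug parameter ships in `inst/extdata/drug_library.yaml`, labeled
literature-order and overridable; none is fitted to any specific trial.

## Numerical choices

- **Quasi-steady nutrient fields** (`oxygen_qss = TRUE`): oxygen, glucose
  and lactate equilibrate within minutes (microvascular exchange rate
  $60 K^{trans}/v_e \approx 30{-}50$/h) while density evolves over days, so
  each outer step solves the steady reaction–diffusion balance by a
  warm-started, positivity-preserving Jacobi iteration (Patankar
  linearization of the Monod sink). The explicit time integrator remains
  available (`oxygen_qss = FALSE`) and the steady solution is checked
  against brute-force time marching in the tests.
- **Drug fields** use operator splitting: exact per-voxel relaxation toward
  $v_e C_p$ (the stiff exchange term integrated analytically), then
  explicit diffusion. This keeps the scheme stable at the 6 h outer step
  without substepping at the exchange rate.
- **Mesh relaxation** inside the engine uses a damping step of
  `0.5 / K_i` ($K_i$ = summed incident stiffness) rather than the module
  default `0.1`, because warm-started increments between mechanics updates
  are small; energy backtracking guarantees monotone descent either way.
  Deformation is resolved on the tumor bounding box (+3 voxels) with outer
  nodes fixed — displacement fields decay quickly away from the tumor, and
  this keeps the mesh small.
- **Fit initialization** for the Tofts model is Ktrans = 0.1/min,
  ve = 0.3, vp = 0.02, with bounds enforcing the physiological invariants;
  non-convergence returns a flagged result rather than an error, and an
  all-zero series short-circuits to Ktrans = 0.
- **Degenerate inputs**: a baseline volume already below 0.01 cm³
  classifies as pCR (the rule as written fires) with a warning; subgroups
  with a zero denominator are flagged and omitted from metrics, matching
  the convention of not computing a hazard ratio when a group has no
  events.

## The synthetic cohort

No patient images are distributed with the package, so a generator supplies
phantoms and cohorts with the statistical structure the validation design
assumes:

- **Phantoms** are ellipsoidal (optionally multifocal or rim-enhancing with
  a necrotic, avascular core), embedded in fat with a one-voxel background
  shell and a branching vessel path touching the tumor margin. Perfusion
  heterogeneity is smoothed white noise (repeated neighbor averaging — a
  Gaussian filter by the central limit theorem) rescaled to the requested
  Ktrans moments. Default diameters 8–14 mm at 2 mm voxels keep a full
  cohort simulation within minutes on one CPU; the geometry scales to
  0.5 mm voxels unchanged.
- **Cohorts** mirror the published validation cohort's marginals: subtype
  mixture 41% TNBC / 17.4% HR−/HER2+ / 16.7% HR+/HER2+ / 24.9% HR+/HER2−,
  four regimen classes (HER2-directed regimens only for HER2+ cases, 93%
  anthracycline use in HER2− cases), dose reductions in ~20% of cases, and
  two follow-up scans (days 42 and 84).
- **Ground truth is not the predictor.** Observed outcomes come from
  re-simulating each case with lognormally perturbed sensitivity
  multipliers (sdlog 0.25) plus 4% label noise, so sensitivity and
  specificity below 100% arise naturally and the evaluation layer has a
  non-degenerate target. Survival times are exponential with a much lower
  event hazard for observed-pCR cases (0.004 vs 0.05 per year), echoing the
  prognostic separation qualitatively — no attempt is made to match
  published hazard ratios quantitatively.
- **Calibration.** The per-subtype lognormal sensitivity distributions were
  set once so the simulated pCR rate sits near the design rate of ~35%
  (the published cohort's 50/144), with the qualitative subtype ordering
  (HER2+ highest, HR+/HER2− lowest) preserved.

What passing tests on this cohort do **not** show: that the simulator
predicts real patients. The phantoms have no MRI signal physics, no
registration error, no segmentation ambiguity, and their ground truth is
generated by a perturbed copy of the same model family. The synthetic
cohort validates the *machinery* — transport, PK/PD, the decision rule, and
above all the statistical layer — not clinical accuracy.

## Statistical layer

Sensitivity/specificity/accuracy come with exact Clopper–Pearson intervals
(`qbeta` quantiles; the published overall and HER2+ rows reproduce to one
decimal from their confusion counts). AUROC is the Mann–Whitney pair
statistic with ties counted ½ (verified against a brute-force all-pairs
oracle and against pROC), with a 1000-replicate percentile bootstrap CI
(percentile, not BCa — the simplest choice consistent with "1000×
bootstrapping"). The clinical comparator is a threefold stratified
cross-validated logistic regression on one-hot-encoded covariates; every
case is scored exactly once by a model never trained on it. Survival
endpoints use the log-rank test, Kaplan–Meier survival at a 5-year horizon,
and a hazard ratio from a single-covariate proportional-hazards fit —
flagged, not computed, when a group has no events. Correlations use the
Fisher transformation with $z = \mathrm{atanh}(r)\sqrt{n-3}$. Percentages
are rounded to one decimal for display only; CSVs retain raw proportions.
No multiplicity correction is applied to the exploratory outcome analyses.

A deliberate omission: no a-priori power calculator is provided. The
published sample-size statement could not be matched to a standard formula
from its stated inputs, and guessing the method would be worse than leaving
it out.

## Problem sizes

The shipped defaults run the numerical checks on 31³ lattices, the
steady-state cross-check on 10³, mesh properties on 4³–8³ meshes, and the
end-to-end cohort at n = 144 with two simulations per case (predictor and
perturbed truth) at 2 mm voxels — a few minutes on a single CPU. These
sizes are the package's desk-scale design point; the imaging-native 0.5 mm
resolution is supported by the same code paths for single cases.

## Known limitations

- Because microvascular exchange is fast (minutes) relative to plasma
  kinetics (hours–days), equilibrium tissue exposure of small-molecule
  drugs is close to $v_e C_p$ regardless of `Ktrans`, so the kill field is
  nearly spatially uniform and a single case's detectable-volume
  trajectory is step-like: near-simultaneous threshold crossing rather
  than the gradual shrinkage real tumors show. Response heterogeneity in
  this model therefore lives mostly *across* cases (sensitivity
  multipliers, `ve` variation, necrotic cores), not within one tumor.
  Capturing intratumoral exposure gradients would require cellular
  uptake/binding sinks, which are not modeled.
- Growth cannot expand the detectable volume in `bookkeeping` mechanics
  mode (density is capped at carrying capacity and cannot colonize empty
  voxels without deformation); treatment response — shrinkage — is the
  intended regime for that mode.
- Lymph-node response is not modeled; predictions concern the breast
  lesion only.
- The Monod surrogate tracks two nutrients and lactate; CO2/formate
  bookkeeping, pH effects and flux-balance analysis are out of scope.
- Drug combination defaults to additive independent action; synergy and
  antagonism are not modeled.
- Signal-intensity-to-concentration conversion is out of scope: synthetic
  DCE inputs are already concentrations.
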