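---
title: "Photon isoeffective dose modelling for BNCT of glioblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon isoeffective dose modelling for BNCT of glioblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnctdose)
```

## The problem and the model

BNCT irradiates boron-loaded tissue with low-energy neutrons; the
10B(n,α)7Li capture reaction deposits high-LET dose selectively in cells
that carry boron. The absorbed dose is the sum of components with very
different biological effectiveness — boron-capture products, neutron-induced
charged particles (protons from nitrogen capture and recoils), and photons
(mostly 2.2 MeV hydrogen-capture gammas). Clinical interpretation requires a
photon-equivalent dose.

Two conversions are implemented side by side:

* the **RBE-weighted dose** `w_B D_B + w_n D_n + w_γ D_γ` with fixed
  factors (the clinical convention; `rbeWeightedDose()`), and
* the **photon isoeffective dose**: the photon dose giving the same cell
  survival as the mixed field under the modified linear-quadratic (MLQ)
  model (`isoeffectiveDose()`).

The MLQ reference-survival model is
`S_R = exp[−(α_R D + β_R G_R(θ) D²)]`. The Lea–Catcheside factor
`G ∈ (0, 1]` scales the quadratic (sub-lethal, pairwise) damage term for
repair occurring while the dose is still being delivered. For constant-rate
delivery over `θ` minutes and a single first-order repair time `t0`,

`G(θ, t0) = (2 t0/θ) [1 − (t0/θ)(1 − e^(−θ/t0))]`,

and sub-lethal damage repair follows dual kinetics: a convex combination of
`G` at a fast and a slow repair time with LET-class-specific proportions
(`gSingle()`, `gDual()`). The mixed-field log-survival adds the three
per-component terms and three synergy cross terms
`2 G_ij √(β_i β_j) D_i D_j` (`survivalMixedField()`); inverting the
survival equality gives the closed-form isoeffective dose. We verify the
closed form against bisection on the survival equality (relative error
below 1e−8 across 1000 random mixed fields) and the `G` closed form
against brute-force numerical evaluation of the double integral (relative
error below 1e−6 for `θ` from 0.1 to 10⁴ min).

## Parameters and their meaning

| parameter | units | default | meaning |
|---|---|---|---|
| `alpha`, `beta` | Gy⁻¹, Gy⁻² | per component | LQ radiosensitivity of each radiation |
| `t0Fast`, `t0Slow` | min | 91, 1238 | characteristic SLD repair times (U87, from bi-exponential foci decay) |
| `fracFastLowLET` | – | 0.77 | proportion of sub-lesions repaired by the fast kinetics, photons |
| `fracFastHighLET` | – | 0.2 | same, high-LET components (literature value) |
| endpoint survival | – | 0.01 | the 1% survival level at which RBE/CBE factors are quoted |
| `RBEWeights` | – | 3.8 / 3.2 / 1 | clinical CBE(boron) / RBE(neutron) / photon factors |
| boron concentration | ppm | 40 tumor / 13.6 brain | scales the per-ppm boron dose grid per ROI |
| prescription | Gy(RBE), fraction | 2.5, 0.5 | normal-brain DVH constraint that fixes the irradiation time |

The glioblastoma parameter set `gbmParameters()` (photon 0.21/0.02, neutron
0.5/0.5, boron 3.0/0, Co-60 reference) is the package's built-in U87 set.
Times are minutes and doses Gy throughout; `θ = 0` encodes an acute
exposure, for which every `G` is exactly 1 (the closed form is continuous
there, and the implementation switches to a series expansion for
`θ/t0 < 1e−4` to avoid cancellation).

## Design choices where the design was open

**Mixed-field exponent.** The survival model's exponent is taken to be
exactly the bracketed expression inside the isoeffective-dose closed form
(component linear terms, G-scaled quadratic terms, and the three
`√(β_i β_j)` cross terms). This is the only reading that makes the survival
model, the survival-equality definition and the closed form mutually
consistent.

**Cross-term G factors.** No established rule exists for the protraction
factor of a synergy term between components of different LET class. All
components are delivered simultaneously over the same `θ`, so each cross
factor is computed with `gDual()` over the shared duration using the
arithmetic mean of the two components' fast-fraction proportions. At
BNCT-typical durations (10–35 min) every factor lies in 0.97–0.99, so the
choice moves results by well under 1%.

**Reference protraction.** RBE/CBE factors and the isoeffective dose
default to an acute reference (`G_R = 1`); a `fixed_rate` mode is provided
in which the reference delivery time is `D/rate` and the closed form is
iterated to self-consistency (relative tolerance 1e−8, verified against the
survival equality). The acute default matches how endpoint factors are
conventionally derived when the reference delivery time is not part of the
quoted quantity.

**Fit space and weighting.** Survival curves are fitted on log-survival,
which linearises the exponent; weights are vertical (survival) uncertainties
transformed to the log scale (`σ_y = σ_S/S`). An `effective` weighting
option folds per-point dose uncertainties (in practice dominated by the
boron concentration measurement) into the weights through the model
gradient, with one reweighted refit. The reference-curve problem is then
linear in (α, β) and is solved exactly under non-negativity constraints by
active-set enumeration; its covariance has the closed WLS form.

**Square-root beta parameterisation.** The joint beam-only/BPA-BNCT fit
estimates (α_n, β_n, α_B, β_B) with the photon parameters fixed from the
reference fit. Because the synergy terms involve `√(β_i β_j)`, the
optimiser works on `√β` internally: the objective stays smooth at the
`β = 0` boundary, where the natural-scale parameterisation has an infinite
derivative. Estimates are reported on the natural scale with delta-method
sigmas; a parameter that lands on its bound is flagged
(`boundaryFlags()`) and receives a one-sided interval. With the U87-like
data the boron quadratic term lands on the zero bound, as expected for a
purely high-LET component.

**Multi-start for the foci fit.** The bi-exponential repair fit has a
notoriously shallow objective along the slow component (its sampling
uncertainty is of the same order as the estimate), so the fit is
multi-started on a fixed grid of 27 starting points spanning the observed
time range and the labels are swapped post hoc to enforce `t0f ≤ t0s`.

**Confidence intervals.** Default intervals are linearized (covariance
`(JᵀWJ)⁻¹` with known weights, scaled by the reduced residual sum otherwise)
at the 68% level conventionally used for radiobiological parameters; a
seeded parametric bootstrap is available and agrees with the linearized
half-widths within 20% on well-conditioned fits. Singular directions are
reported as `NA` rather than numbers.

**Reporting conventions.** Dose summaries are conventionally rounded to
0.1 Gy-eq and comparison percentages to integers;
`percentDifference(reference, other)` uses the reference value as the
denominator. DVHs use 256 uniform bins from 0 to the ROI maximum by
default; the cumulative curve is defined with `≥`, starts at 1 and ends at
0 just above the maximum. `D(v)` read-offs interpolate the cumulative
curve, so their resolution is about half a bin width — use more bins when
reading off points on a wide dose range.

## What the synthetic generators emulate — and what they do not

`generateClonogenicAssay()` draws colony counts as
`Poisson(cellsSeeded × platingEfficiency × S)` at the study's dose designs
(a ~1 Gy/min photon dose ladder; 10-min reactor irradiations at four
power steps with ~10% photon contamination in the beam-only condition, a
boron-dominated BNCT condition) and perturbs the nominal boron dose by a
relative Gaussian error to emulate the boron-concentration measurement.
Poisson counting is the standard clonogenic statistics; seeding densities
increase with dose as in laboratory practice. `generateFociSeries()` adds
Gaussian noise to the bi-exponential decay. `generatePhantomField()` builds
a water-equivalent block with exponentially attenuated component dose-rate
grids (boron stored per ppm) and a shallow spherical tumor; its default
rates are chosen so that the prescription-limited irradiation time lands in
the clinical tens of minutes and the tumor receives boron doses in the
clinically reported tens of Gy(RBE).

None of these claim anatomical or transport realism: there is no neutron
transport, no scatter, no anatomical geometry, and boron is uniform within
an ROI. Consequently, passing tests demonstrate the correctness of the
model arithmetic, the fitting machinery and the conversion/reporting chain
— not agreement with any patient-specific dose distribution, which requires
the clinical grids and Monte Carlo transport upstream of this package.

## Numerical choices and degenerate inputs

* `G` series expansion below `θ/t0 = 1e−4`; exact 1 at `θ = 0`.
* `doseAtSurvival()` uses the stable quadratic root and a linear branch at
  `β = 0`; `α = β = 0` is an error (no solution), `S = 0` is rejected.
* Bounded least squares: active-set enumeration (reference curve) and
  `nls.lm` with box bounds (mixed field, foci), `ftol = ptol = 1e−15`,
  multi-start; noiseless model data are recovered to ~1e−6 relative or
  better.
* Empty ROIs, shape mismatches, zero dose rates at the prescription point,
  and missing boron in the BNCT condition are rejected with specific
  errors rather than propagating NaNs.
* All generators are pure functions of (inputs, seed) via an isolated RNG
  scope; they do not disturb the caller's RNG stream.

## Problem sizes used in the test suite

The suite fits noiseless and Poisson-noise assays (5 reference + 4 + 4
reactor points, 3 replicates), runs 2000-replicate coverage checks of the
68% intervals, 150-replicate foci-recovery studies, 1000 random
mixed-field inversions against the bisection oracle, and phantom grids of
24 × 24 × 40 voxels — sizes at which the whole suite completes in well
under a minute while keeping Monte-Carlo error on empirical coverage near
one percentage point.

## Known limitations

* The model treats boron as uniformly distributed within an ROI;
  sub-cellular boron micro-distribution effects are outside the model's
  formalism.
* Normal-tissue conversion uses fixed RBE/CBE weights only (as in clinical
  prescriptions); no isoeffective normal-tissue model is provided.
* The two neutron dose grids (thermal capture and fast recoil) are summed
  into a single neutron component before conversion; they are kept separate
  in the data model because treatment-planning systems emit them
  separately.
* Patient-level absolute dose tables cannot be reproduced without the
  clinical dose matrices; the package validates the conversion chain on
  synthetic phantoms instead.
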