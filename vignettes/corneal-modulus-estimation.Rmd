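---
title: "Estimating corneal Young's modulus from clinical tonometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating corneal Young's modulus from clinical tonometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneamech)
```

## The model and its assumptions

Goldmann applanation tonometry infers intraocular pressure (IOP) from the
force needed to flatten a fixed corneal area (7.35 mm², about 1.5 gf). The
reading therefore mixes the true pressure with the cornea's own mechanical
response: a thick or stiff cornea resists flattening and reads high. The
Pascal dynamic contour tonometer (PDCT) matches the corneal contour instead
of flattening it, and its reading is treated throughout as the true IOP.

This package models the cornea as a thin spherical shell of anterior radius
$R$ (mm), central thickness $t$ (mm) and Poisson's ratio $\nu = 0.49$
(near-incompressible tissue), linearly elastic over the small deformation
applanation produces (~150 µm of central indentation). Two dimensionless
coefficients summarise the shell's response:

$$B = 0.6\,\pi R (R - t/2)\sqrt{1-\nu^2}\,/\,t^2, \qquad
  C = \frac{2 \pi R (R - t/2)}{(1-\nu)\,A\,t},$$

and the Young's modulus in MPa follows from the paired readings as

$$E_{calc} = \frac{B \cdot IOPG - C \cdot IOPT}{7500}.$$

The Goldmann-only estimator $E_{iopg}$ replaces the measured $IOPT$ with a
corrected pressure $IOPT_{calc}$ derived from the *calibration cornea*
assumption: for the cornea of average curvature and thickness, the Goldmann
reading is taken to equal the true pressure. Structural stiffness is
$k = t\,E$ (N/mm); MPa·mm and N/mm are the same unit.

Assumptions worth keeping in view: linear elasticity (no viscoelastic,
hyperelastic or anisotropic behaviour), a spherical shell (no astigmatic or
ectatic geometry), contour tonometry as ground truth, and instantaneous
loading. None of these hold exactly in vivo; they are the price of a
closed-form method that runs on routine clinical measurements.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `poisson_ratio` | 0.49 | — | tissue incompressibility; enters $B$ as $\sqrt{1-\nu^2}$ and $C$ as $1/(1-\nu)$ |
| `applanation_area` | 7.35 | mm² | Goldmann applanated area; $C \propto 1/A$ |
| `mmhg_per_mpa` | 7500 | — | pressure-unit divisor; moduli rescale inversely, $IOPT_{calc}$ is unaffected |
| `shell_factor` | 0.6 | — | dimensionless multiplier in $B$ |
| `quality_max` | 3 | grade | worst acceptable contour-reading grade (1 best, 5 worst) |
| `diff_threshold` | 4 | mmHg | tonometer-disagreement count threshold (absolute, inclusive) |
| calibration geometry | cohort means | mm, µm | recomputed per run; explicit `(R, t)` override supported |

Lengths are held internally in millimetres because the shell equations are
stated in mm; readers convert micrometre pachymetry by ÷1000 and dioptre
keratometry by $R = 337.5/K$.

## Design choices where the algebra was open

**Coefficient parses.** Typeset shell formulas are easily mis-read where
fraction bars and radicals stack. We fixed the algebraic readings above by a
plausibility audit (`audit_parses()`): each candidate parse is evaluated at
reference cohort-mean inputs (R = 7.75 mm, t = 549.9 µm, IOPG = 15.06,
IOPT = 16.89 mmHg), and a parse is accepted only if the implied
two-tonometer modulus is physiologically plausible (0 < E ≤ 0.5 MPa) *and*
the calibration-cornea Goldmann-only modulus falls in the band reported for
normal young corneas (0.24–0.34 MPa). The default parse gives
E ≈ 0.234 MPa; moving the factor 2 of $C$ into the denominator (or attaching
it to $(1-\nu)$ in the numerator) collapses $C$ to ≈ 44–46 and inflates the
modulus above 0.5 MPa; dropping the square root in $B$ or squaring the chord
term fails the calibration-cornea band. Only the default combination
survives. The rejected parses remain callable behind the `parse` arguments
so the audit is reproducible.

**The corrected-pressure variant.** The correction
$IOPG\,(B_c - C_c + C)/B$ (the `printed` variant) *raises* the corrected
pressure for thick corneas, which contradicts both the physical direction
(Goldmann over-reads thick corneas, so their true pressure is lower than
the reading) and the negative correlation between corrected pressure and
thickness observed in cohorts. The subscript-swapped form
$IOPG\,(B - C + C_c)/B_c$ (the `consistency` variant) moves in the correct
direction and is the default; both variants reduce exactly to $IOPG$ at the
calibration cornea, and both are exposed.

**Calibration cornea.** "Average values" is implemented as the analysed
cohort's mean curvature and thickness, recomputed per run, with an explicit
override for reproducing fixed published calibrations. The choice matters:
every $E_{iopg}$ value is conditional on it.

**Negative moduli.** $E_{calc} \le 0$ is possible whenever
$C \cdot IOPT > B \cdot IOPG$ (e.g. a very discordant tonometer pair). Such
records are flagged and retained, never clamped or silently dropped; the
cohort summary reports the flag counts.

## The Goldmann-error decomposition

With the inverse relation $IOPG = (7500E + C\,IOPT)/B$, the predicted
reading error relative to the calibration cornea splits into components over
a thickness grid (default 450–650 µm in 5 µm steps — a 200 µm range centred
near the population mean; endpoints are flags, not facts):

* **Effect of CCT** — modulus and true IOP fixed at calibration-cornea
  anchors (the Goldmann-only modulus at the cohort-mean reading, and the
  cohort-mean contour pressure), thickness varied. Zero at the calibration
  thickness, increasing in $t$: thick corneas over-read. Anchored at the
  reference cohort means the span over the grid is ≈ 8.3 mmHg.
* **Effect of E** — geometry fixed at calibration, modulus varied with
  thickness through a cohort-fitted linear mapping. Two propagation routes
  are provided. `"model"` (default) pushes the modulus change through the
  shell relation at the calibration coefficients, i.e. $7500\,\Delta E/B_c$
  ≈ 23.8 mmHg per MPa. `"regression"` divides the modulus change by an
  empirical modulus-on-IOPG regression slope, ≈ 36 mmHg per MPa at the
  reference cohort's moments. The regression route is the construction that
  reproduces the figure-scale modulus effect (≈ 11 mmHg over the grid)
  reported for cohorts of this kind; the model route is the
  internally-consistent shell prediction. They differ because the empirical
  modulus–pressure slope absorbs between-subject covariance the shell
  relation does not contain; we expose both rather than blending them.
* **Net** — either the pointwise sum of the components or, with a cohort
  attached, the empirical regression of (IOPG − PDCT) on CCT evaluated on
  the grid. In normal young cohorts the two components run in opposite
  directions and largely cancel, which is why IOPG appears uncorrelated
  with CCT even though each factor alone moves it by many mmHg.

Sign convention: error = predicted reading minus the calibration-point
reading, so positive means over-reading.

## The synthetic-cohort generator

`synthetic_spec()` fixes the study conditions: 100 subjects, curvature
7.75 ± 0.26 mm, thickness 549.9 ± 32.8 µm jointly bivariate normal with
corr(t, R) = 0.23, true IOP 16.89 ± 2.49 mmHg, and a latent true modulus
0.29 ± 0.06 MPa, all truncated to validity. Readings follow the forward
observation model: the Goldmann mean is the shell prediction for the
subject's latent state, the contour mean is the latent true IOP, with
replicate counts per the clinical protocol (2 keratometry, 3 pachymetry,
3 Goldmann, 3 contour with quality grades drawn 0.38/0.38/0.19/0.03/0.02
over grades 1–5 to exercise the quality filter). Instrument noise defaults
to a quarter of each population SD — population SDs describe between-subject
spread, of which instrument noise is plausibly a minor share; this split is
a declared assumption, overridable per spec key. Both eyes share a latent
state and differ only in noise. All randomness is fixed by a single seed.

What the generator deliberately does **not** emulate: a calibration offset
between the tonometers (in real cohorts the contour tonometer reads
~1.8 mmHg above Goldmann *at the average cornea*, which the self-consistent
forward model cannot produce), any latent modulus–thickness correlation, and
diurnal or inter-observer effects. Consequently a synthetic cohort
reproduces the shell model's internal structure — zero-noise cohorts recover
the latent modulus exactly, estimator means land near the latent mean — but
not every empirical statistic of a real cohort: its mean $E_{calc}$ sits
near the latent 0.29 MPa rather than the 0.25 MPa a real tonometer offset
produces, its corrected-pressure gap is small, and tonometer-disagreement
counts are lower. Passing recovery tests therefore validates the estimator
pipeline, not the forward model's completeness as a description of real
eyes; the cohort-reproduction acceptance block documents exactly which
statistics need real data.

## Numerical choices

* Closed-form operations are tested against independently factored
  evaluations to 1e−12 relative; statistics against brute-force moment
  oracles to 1e−9; forward/inverse round-trips to 1e−10.
* Truncated sampling uses rejection with at most 100 resampling rounds, then
  aborts with a generation error (reached only for pathological specs).
* Geometry outside R ∈ [6.5, 9.5] mm or t ∈ [0.35, 0.75] mm warns but is not
  rejected — a plausibility screen, not a validity claim.
* Per-subject CSV output uses 17 significant digits so a reload reproduces
  the analysis bit-for-bit.
* The recovery study uses 50 replicates of n = 100 for the bias check and
  10 replicates per noise level for the monotonicity check; these sizes give
  Monte-Carlo standard errors comfortably below the effects being asserted.
* Degenerate inputs are signalled, not propagated as NaN: constant series in
  correlations, zero-variance paired differences, non-positive pressures,
  and empty grids all raise typed errors.

## Known limitations

The method is linear elastic and the modulus it returns is a secant-like
effective stiffness at applanation strain, not a material constant valid at
other strains. The calibration-cornea assumption restricts $E_{iopg}$ to
normal corneas; oedema, refractive surgery or keratoconus break it, and
$E_{calc}$ (which needs the contour tonometer) should be used instead. The
left-eye convention of the cohort pipeline avoids inter-eye correlation
inflating sample size, at the cost of discarding half the data. Correlation
tables report raw two-tailed p-values with no multiple-testing correction,
mirroring standard clinical reporting for this analysis; treat borderline
stars accordingly.
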