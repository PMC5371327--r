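---
title: "Building and evaluating a weighted composite progression endpoint"
author: "retcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating a weighted composite progression endpoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retcomp)
```

## Scope and model

`retcomp` measures macular degeneration progression in Stargardt-type
dystrophies from five routinely collected quantities per eye-visit:
decimal best-corrected visual acuity (BCVA), questionably and definitely
decreased autofluorescence areas (QDAF, DDAF; mm²) and transverse
ellipsoid-zone and external-limiting-membrane loss (EZ, ELM; mm). The
package's premise is spatial: all five can be read as the eccentricity ε
(degrees from the foveal center) that a degenerative front has reached, so
they become commensurable and can be averaged.

The analysis chain is: standardize to ε; form per-biomarker changes from
each eye's baseline; combine them into a weighted composite ΔC; fit the
zero-intercept random-slope model

$$\Delta C_{ij}(\Delta t_{ik}) = (s + s_i + s_{ij})\,\Delta t_{ik} + E_{ijk},$$

with $s_i \sim N(0, \sigma_p^2)$ per patient, $s_{ij} \sim N(0,
\sigma_e^2)$ per eye within patient, $E_{ijk} \sim N(0, \sigma^2)$, all
independent; rank weightings by the responsiveness criterion
$\mathrm{MSDR} = s/\mathrm{RMSE}$; validate by leave-last-visit-out
prediction; and estimate trial power by Monte-Carlo simulation of a
paired-eye design. Manual image grading is upstream of the package; the
package starts from the graders' numbers (and provides their agreement
statistics).

## Standardization: constants and edge cases

Two constants govern the conversions, fixed to the published values:
1° of eccentricity ≈ 0.3 mm of retina, and decimal acuity decays by a
factor 1/1.2 per degree. Areas are summarized by their circular-equivalent
radius, transverse losses by half the measured span (the span is a
diameter through the fovea). All transforms are strictly monotone with
exact algebraic inverses; the test suite requires round trips to 1e-9.

Acuity better than 20/20 would map to a negative eccentricity; since ε is
a non-negative spatial extent, such values are clamped to 0° with a
warning. Non-numeric acuity categories (counting fingers, hand movements)
are rejected rather than imputed — no published mapping to decimal acuity
is assumed. Missing measurements propagate: no value is ever imputed, and
each downstream stage defines its own handling.

## The composite and its weights

`composite_change()` divides the weighted sum of available per-biomarker
changes by the total weight of the *available* biomarkers. This
renormalization is what lets eyes whose EZ loss outgrew the OCT scan keep
contributing; it also makes the composite invariant to rescaling all
weights, so weights are conventionally reported as percentages summing
to 100.

Weights live on a simplex grid (default 5% steps): 20 units over five
biomarkers, `choose(24, 4) = 10626` combinations, enumerated in
deterministic lexicographic order with exact integer units internally so
no floating-point drift can reorder ties. `optimize_weights()` refits the
progression model for every combination and takes the MSDR argmax among
converged fits, ties breaking to the earliest combination. One published
inconsistency is worth recording: the source study's results text gives
the optimum as 0/25/5/55/15% (BCVA/QDAF/DDAF/EZ/ELM, summing to 100)
while its summary table prints 15% QDAF — summing to 90. The package
default (`optimal_weights()`) follows the text version; the discrepancy is
documented here, not resolved.

## Fitting: numerics

The model has one fixed parameter and three variances, with likelihood
profiled down to the two variance *ratios* $\gamma_p = \sigma_p^2/\sigma^2$
and $\gamma_e = \sigma_e^2/\sigma^2$. These are optimized on the log scale
(which enforces non-negativity), from fixed deterministic starts — the OLS
slope and unit ratios — by `nlminb` with a relative objective tolerance of
1e-10, bounded in $[e^{-30}, e^{25}]$. A ratio at the lower bound is
reported as a variance pinned at zero with a warning, not an error. Given
the ratios, the slope is the GLS estimate and $\sigma^2$ the (restricted)
residual mean square in closed form. REML is the default (matching the
usual mixed-model default of the original analysis software); ML is
available for likelihood comparisons across weightings. The Wald 95% CI on
the slope uses z = 1.959964; the original degrees-of-freedom method is
unknown, which is a documented source of small CI differences.

Design choices that matter:

* **Baseline records are excluded from the fit.** Under a zero-intercept
  change-from-baseline model the Δt = 0 records are identically zero;
  keeping them would deflate the residual variance. Correspondingly, the
  *adjusted RMSE* — the noise scale used by the trial simulation — is the
  root-mean-square of conditional residuals over follow-up records only.
* **Random effects are independent univariate normals** (no covariance
  terms), exactly as the model equation lists them.
* **Degenerate inputs** are handled explicitly: noise-free data short-cut
  to the exact OLS fit with all variances zero; a zero residual SD makes
  the MSDR infinite with a flag rather than an error.
* The whole fit is cross-checked against `lme4` in the test suite (same
  model, agreement to ≤ 1e-4 on all parameters and BLUPs); `lme4` is never
  the implementation, so the check stays two-routed.

The exhaustive grid search re-uses per-biomarker delta columns and caches
the design structures per missingness pattern (there are at most 31), and
each refit warm-starts from the last converged variance ratios of its
pattern. The full 10,626-fit search takes about a minute on one CPU.

## Validation protocol

For each eye with at least three visits, the chronologically last visit is
held out; the model is trained on the rest and the held-out composite
change predicted as (BLUP slope) × Δt. Conditional rather than
population-slope predictions are used because only they can reproduce the
per-eye spread a calibration plot shows. Calibration regresses measured on
predicted (prediction on the x-axis, the usual calibration orientation;
the source study does not state its orientation) and reports R² and Wald
CIs. Replication on an external cohort freezes the development weights —
the second cohort gets its own model fit but no re-optimization. Both eyes
of a qualifying patient contribute test points.

## Trial simulation

The simulated trial treats one eye per patient and follows everyone for
`follow_up_years` (default 2). Each eye's increment is its conditional
predicted increment plus independent noise with SD equal to the adjusted
RMSE; the treated eye's increment is reduced by δ = effect × (its own
predicted increment). The published simulation formula writes the noise as
"± adjusted RMSE"; the package reads this as a zero-mean normal draw with
that SD, consistent with the model's residual term, and offers the literal
±-with-equal-probability reading (`noise = "rademacher"`) for sensitivity
analysis. The treated eye is assigned by a fair Bernoulli draw per patient
per replicate, or — as a scenario — the *worse* eye (larger baseline
composite eccentricity) is always treated. The paired analysis is a
two-sided paired t-test on one per-patient between-eye difference; the
non-paired variant randomizes patients 1:1 to treatment vs observation,
analyzes one eye per patient to preserve independence, and uses a pooled
two-sample t-test. Replicates with a degenerate statistic count as
non-rejections and are tallied. Each effect size derives its own sub-seed
deterministically from the design seed, so curves and scenario variants
are reproducible bit-for-bit and comparable across runs. The simulation is
checked against the closed-form noncentral-t power of the paired design on
a homogeneous-slope fit.

## Inter-grader agreement

Lesions are delineated by two independent graders; analysis uses their
arithmetic mean, and pairs differing by more than 1° are flagged for
consensus. `agreement_stats()` reports the mean ± SD absolute difference
and the intraclass correlation. The ICC form is two-way,
absolute-agreement, single-measure (ICC(A,1)) — chosen because absolute
inter-grader differences are the quantity of interest; the consistency
form ICC(C,1) is available by option. Both are computed from the two-way
ANOVA mean squares with McGraw–Wong confidence bounds, and verified
against an independent ANOVA decomposition in the tests. Zero total
variance makes the ICC undefined, signalled by a classed warning and `NA`.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, so every
stage is testable without patient data. Per patient: a number of visits
(development preset 2–4 per eye, validation 2–6), a follow-up span drawn
from the cohort's range (1.13–9.71 and 1.0–10.99 years respectively;
every eye spans ≥ 1 year, the inclusion criterion), and visit dates shared
by fellow eyes. Per biomarker: a patient-level baseline drawn uniformly
from the cohort's published baseline range, with fellow-eye jitter sized
so the between-eye baseline correlation is 0.8 — the correlation is known
to be high but unquantified, so its value is an explicit, documented free
choice. Population slopes (0.31/0.32/0.58/0.38/0.34 °/yr for
BCVA/QDAF/DDAF/EZ/ELM) and residual SDs (3.77/0.14/0.33/0.20/0.17°) are
the published development-cohort estimates. One patient-level and one
eye-level slope deviation (SDs 0.15 and 0.05 °/yr) are drawn per patient
and per eye and shared across biomarkers: they model the patient's overall
progression rate, which makes the weighted composite itself follow the
single-random-slope model exactly — with independent per-biomarker
deviations, the composite's missing-biomarker renormalization would
convert slope heterogeneity into residual inflation whenever the biomarker
composition switches within an eye's series, a structure the analysis does
not assume.

Residual noise is applied on the ε scale at follow-up visits only —
baseline visits are exact, mirroring a change-from-baseline model in which
baseline residuals are identically zero — then everything is floored at 0°
and inverted to raw clinical units, so generated tables exercise the full
parsing and standardization path. EZ loss is set missing whenever its ε
exceeds the scanned half-width (default 9°), emulating lesions that
outgrow the OCT scan; this missingness is informative (large lesions go
missing), as in the real data.

What the generator does *not* emulate: grader error processes (only
additive ε noise), floor effects other than the 0° clamp, non-linear
trajectories, visit-schedule irregularities correlated with disease state,
and any genotype structure. Passing tests therefore demonstrate that the
pipeline recovers the assumed data-generating process, not that real
cohorts satisfy those assumptions.

## Problem sizes used by the tests

The suite fits development-preset cohorts (14 patients, ~50 follow-up
records), runs the full 10,626-combination grid once, uses 100 seeds for
the distributional check on the univariable QDAF MSDR, 200 replicates for
mixed-model parameter recovery (bias within 2 Monte-Carlo SEs on the
variance scale), and 10,000 Monte-Carlo replicates per effect size for the
power checks — the same replicate count as the published power analysis.

## Known limitations

* Patient-level measurements of the original cohorts are not shipped, so
  the published cohort-specific estimates (univariable MSDRs, the 0.41
  °/yr composite slope, hold-out R² of 0.904/0.872, the exact grid argmax)
  can only be recomputed after the user supplies that dataset; the test
  expecting it fails visibly otherwise rather than being skipped.
* The Wald CI and REML defaults approximate, but cannot exactly match, the
  original SAS estimation settings.
* The acuity–eccentricity law is used as stated; the underlying
  psychophysical curve is not re-derived, and no alternative laws are
  offered.
* The composite is a structural surrogate: it is designed to rank
  treatments by effect on progression, not to stand in for
  patient-relevant visual function.
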