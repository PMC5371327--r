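# retcomp

Weighted composite endpoints for measuring retinal degeneration progression
in Stargardt disease and related macular dystrophies.

## The problem

Inherited retinal dystrophies are individually rare and phenotypically
heterogeneous, so phase I/II trials recruit few patients and follow them
briefly. The standard functional endpoint — best-corrected visual acuity
(BCVA) — deteriorates erratically and late, giving a poor signal-to-noise
ratio. Structural imaging, by contrast, shows transition zones that expand
steadily from the fovea outward: atrophy areas on fundus autofluorescence
(questionably and definitely decreased autofluorescence, QDAF/DDAF) and
transverse loss of the ellipsoid zone (EZ) and external limiting membrane
(ELM) on OCT. `retcomp` implements a pipeline that turns these five
measurements into a single, maximally responsive composite endpoint for
small trials, and quantifies the trial power it buys.

## The method

1. **Standardization.** Every measurement is expressed as retinal
   eccentricity ε (degrees from the foveal center; 1° ≈ 0.3 mm):
   - acuity: BCVA = (1/1.2)^ε, so ε_BCVA = log_{1/1.2}(BCVA);
   - atrophy area A (mm²): ε = (1/0.3)·√(A/π), the circular-equivalent radius;
   - transverse loss L (mm): ε = (1/0.3)·(L/2), the diameter's radius.
2. **Composite change.** For eye *j* of patient *i* at follow-up Δt, the
   composite change from baseline is the weighted mean
   ΔC_ij(Δt) = Σ_b w_b·Δε_b / Σ_b w_b over the biomarkers available at both
   visits (missing biomarkers drop out; remaining weights renormalize).
3. **Progression model.** A zero-intercept random-slope mixed model,
   ΔC_ij(Δt_ik) = (s + s_i + s_ij)·Δt_ik + E_ijk, with independent
   patient-level (s_i) and eye-within-patient (s_ij) slope deviations, fit
   by REML.
4. **Weight optimization.** The responsiveness criterion MSDR = s / RMSE
   (population slope over residual SD) is evaluated exhaustively on the 5%
   weight simplex grid — choose(24, 4) = 10,626 combinations — and the
   argmax taken. The packaged optimum is 0% BCVA, 25% QDAF, 5% DDAF, 55%
   EZ, 15% ELM (`optimal_weights()`).
5. **Validation.** For eyes with ≥ 3 visits the last visit is held out and
   predicted from the training fit's conditional (BLUP) slopes; calibration
   is summarized by R² and the OLS slope/intercept of measured on predicted.
6. **Trial power.** A paired-eye trial (fellow eye as within-patient
   control) is simulated: each eye's x-year increment is its predicted
   increment plus N(0, adjusted RMSE²) noise, the treated eye's increment
   reduced by the effect fraction; power is the two-sided paired-t rejection
   rate over 10,000 replicates per effect size.

A synthetic cohort generator (`generate_cohort()`, presets
`cohort_preset("development")` / `"validation"`) reproduces the statistical
structure of the two study cohorts so the whole pipeline runs and is tested
without any patient data.

## Worked example

```r
library(retcomp)

cohort <- generate_cohort(cohort_preset("development", seed = 7))
ecc    <- visit_to_ecc(cohort)                      # standardize to degrees
deltas <- deltas_from_baseline(ecc)                 # changes from baseline
fit    <- fit_progression(composite_deltas(deltas, optimal_weights()))
print(fit)
#> Zero-intercept random-slope progression model (REML)
#>   population slope s : 0.3400 deg/year (95% CI 0.2536 to 0.4264)
#>   sd(patient slope)  : 0.1605 deg/year
#>   sd(eye slope)      : 0.0465 deg/year
#>   residual RMSE      : 0.1042 deg
#>   MSDR               : 3.261
#>   44 observations, 14 patients, 28 eyes
```

The population slope says the composite transition-zone front advances by
about a third of a degree of eccentricity per year; the patient- and
eye-level SDs quantify how progression rates vary between patients and
between fellow eyes; the MSDR of 3.3 is the signal-to-noise ratio the
weighting was optimized for (single biomarkers reach about 2.3 at best).

```r
cal <- validate_composite(ecc, optimal_weights())$calibration
print(cal)
#> Prediction calibration on 12 pairs
#>   R^2       : 0.989
#>   slope     : 0.98 (95% CI 0.92 to 1.05)
#>   intercept : 0.12 (95% CI -0.07 to 0.31)

design <- trial_design(n_patients = 14, follow_up_years = 2,
                       effect_sizes = c(0, 0.25, 0.5), n_sims = 10000, seed = 7)
simulate_trial(fit, adjusted_rmse(fit), design)
#> # A tibble: 3 x 6
#>   effect_size  power   mc_se rejections n_sims degenerate
#> 1        0    0.0463 0.00210        463  10000          0
#> 2        0.25 0.980  0.00140       9801  10000          0
#> 3        0.5  1      0            10000  10000          0
```

A null effect rejects at the nominal 5% level, and a 25% slowing of
progression is detected with high power from only 14 patients over two
years — the case for the weighted composite over acuity alone.

The weight search itself is `optimize_weights(deltas)` (full 5% grid,
about a minute on one CPU) and `msdr_profile()` gives the per-biomarker
envelope of attainable MSDRs.

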