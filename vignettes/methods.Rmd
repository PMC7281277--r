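---
title: "Predicting diurnal urinary cortisol from volatile metabolite profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting diurnal urinary cortisol from volatile metabolite profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocortisol)
```

## The modelling problem

Total free urinary cortisol (µg per void) follows a diurnal rhythm, and
urine headspace carries hundreds of volatile organic compounds (VOCs)
whose abundances co-vary with metabolic state. `vocortisol` implements a
pipeline that regresses log10 cortisol on standardized log10 VOC
abundances with sex and time-of-day interaction terms:

$$\log_{10}(\text{cortisol}) = \beta_0 + \sum_j \beta_j x_j +
\sum_{(j,k)} \gamma_{jk}\, x_j d_k + \varepsilon,$$

where $x_j$ are log10-transformed, centred, scaled feature abundances
and $d_k \in \{\text{Male}, \text{Morning}, \text{Afternoon}\}$ are
binary dummies (reference cell: a female evening sample). The package
ships both the machinery to fit such models from scratch and a frozen
22-coefficient published predictor (14 metabolite terms, 7 interactions,
intercept 0.496 log10 µg) that can be applied to new, appropriately
standardized samples.

## Preprocessing chain

The pipeline applies, in order: blank/early-elution filter → PQN →
presence filter → cortisol outlier removal → log10/centre/scale. The
rationale for this order is that sample-level dilution normalization
should see the sample's full (artifact-free) spectrum before features
are pruned, and standardization parameters must be computed on the final
analysis set so they can be frozen and reused.

* **Blank/early filter.** Features eluting before 358 s in the first
  dimension (solvent front region) or flagged in blank runs are removed.
  The boundary is closed on the right: a feature at exactly 358 s is
  kept.
* **PQN.** The reference spectrum is the per-feature median over samples
  with the feature observed (the classic median-spectrum formulation, no
  prior integral normalization). Each sample's quotient is the median of
  its abundance/reference ratios over observed features; all observed
  abundances are divided by it; missing entries stay missing. PQN
  idempotence and exact dilution recovery hold on dilution-dominated
  data (rows proportional to a common spectrum) — which is precisely the
  phenomenon PQN models; on arbitrary tables the reference spectrum
  itself shifts and both properties hold only approximately. The test
  suite asserts the exact properties on dilution-structured tables and
  an exact unit-median-ratio invariant on noisy cohorts.
* **Presence filter.** Features observed in at least 50% of samples are
  retained (ties at the boundary kept). The threshold is configurable.
* **Outlier removal.** Samples with cortisol above 45 µg (the adult
  healthy reference ceiling) are dropped by rule. Because one historical
  exclusion (44.3 µg) falls *below* that ceiling and no numeric rule
  reproduces it, the filter also accepts an explicit exclusion list
  rather than guessing a tighter criterion.
* **Imputation and standardization.** Remaining missing entries are
  treated as left-censored at the detection limit and imputed with half
  the feature's minimum observed value (strategies `min` and a fixed
  `value` are available). Features are then log10-transformed, centred
  and scaled with the sample (n−1) standard deviation; the per-feature
  means/SDs and PQN quotients are stored so a frozen model can be
  applied to new data (`apply_standardization()`).

## Factor screen

`two_way_anova()` tests sex, time of day and their interaction on (by
default) log10 cortisol, using Type-II sums of squares: outlier removal
unbalances the design slightly, and Type-II is the standard choice when
main effects are the question; on balanced designs it reduces to the
textbook decomposition (asserted against a cell-means oracle in the
tests). Factors with p < 0.05 become the interaction factors offered to
the model search. The response scale is exposed as a flag; log10 is the
default for consistency with the final model. A constant response is
reported as F = 0, p = 1 for every source rather than an error. The
screen deliberately ignores the repeated-measures structure (three
samples per subject), mirroring the plain two-way ANOVA convention of
the workflow it implements; a mixed-effects screen is out of scope.

## Bootstrapped elastic-net stability selection

`bootstrap_select()` repeats, for `n_iter` (default 250) iterations:

1. Split **subjects** (never samples) 80/20 into train/test, so the
   three samples of one subject can never straddle the split. The
   default is subsampling without replacement — the 48/12 subject
   arithmetic of an 80/20 split matches subsampling — with a
   with-replacement bootstrap available by configuration.
2. Fit the elastic-net path (α = 0.5, mixing lasso and ridge) on the
   training samples. The solver is `glmnet`, the field-standard
   coordinate-descent implementation; the objective is
   $\mathrm{RSS}/(2n) + \lambda(\alpha\|\beta\|_1 +
   (1-\alpha)\|\beta\|_2^2/2)$ with an unpenalized intercept. The
   penalty grid is 100 log-spaced values from the data-driven
   $\lambda_{\max}$ down to $10^{-4}\lambda_{\max}$.
3. Choose λ by minimizing the held-out test MSE (an inner
   cross-validation rule is the natural alternative; the held-out rule
   uses the stated 80/20 split directly).
4. Record the features with nonzero coefficients at that λ.

Counts over iterations give selection frequencies; `top_k()` returns the
k most frequently selected features, breaking ties by larger mean
absolute coefficient, then lower column index, so results are
deterministic. Standardization is computed once on the full analysis set
rather than per split — this mirrors the postprocess-then-select
ordering of the original workflow and is a known, documented departure
from strict cross-validation hygiene. Iterations with a degenerate
(zero-variance) training response are skipped; more than 10% skips is an
error.

## Stepwise model selection

`build_design()` assembles candidate main effects, the dummy main
effects, and all candidate × dummy products. `stepwise()` performs
greedy single-term moves minimizing AICc (or BIC):

* $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$,
  $\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$,
  $\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$, where $k$ counts the
  intercept and slopes but not the error variance — the constant drops
  out of comparisons and matches the convention of mainstream
  statistical environments.
* The move with the largest criterion decrease is accepted; ties break
  on the earlier term label; the search stops when no move improves.
* With `hierarchy = TRUE` (default) an interaction may enter only while
  its **metabolite** main effect is present, and a metabolite cannot
  leave while its interaction remains. Dummy main effects are ordinary
  terms: the published final model retains interactions without dummy
  main effects, so requiring full hierarchy on dummies would exclude it.
* `direction = "both"` (default) starts from the intercept-only model
  and considers adds and drops; `"backward"` starts from the full
  design.

`fit_ols()` provides the final inference: coefficients by QR, standard
errors from $\hat\sigma^2 (X'X)^{-1}$, 95% CIs and two-sided t-tests on
n − k residual degrees of freedom, and Benjamini–Hochberg adjusted
p-values computed over all terms of the final model (the adjustment
family reported per term in the frozen predictor's tables).
`compare_models()` ranks competing fits by AICc with BIC deciding ties
and flags models with more than n/3 coefficients as overfit.

## Diagnostics

`compute_diagnostics()` emits the data behind the standard plot suite
(residual vs. fitted, QQ, histogram, lag, drift, added-variable) plus:

* **VIF** per term, computed from the inverse predictor correlation
  matrix, with perfect collinearity reported as a capped sentinel
  (≥ 1e6); the pass flag uses the conventional cutoff of 5.
* Formal backstops for the visual checks: Shapiro–Wilk for residual
  normality and Breusch–Pagan for homoskedasticity, both at α = 0.01 so
  that only gross violations flag.
* Standardized residuals use internal studentization,
  $r_i / (\hat\sigma\sqrt{1-h_{ii}})$.

`subgroup_ttests()` compares each model metabolite between sexes within
each timepoint and between timepoint pairs within each sex — a family of
9 comparisons per metabolite — using Welch's unequal-variance t-test by
default (the safer reading of an unqualified "unpaired t-test"; pooled
variance by flag), with BH-FDR control applied once over the whole
family at FDR 0.10. `residual_summary()` reports per-group residual
ranges and means with their ratio-scale µg back-transforms $10^r$ at 3
significant figures.

## The frozen published predictor

`published_model()` loads a versioned JSON coefficient table (14 main
terms, 7 interactions, intercept) validated against a checksum at load
time; the coefficients are data at printed 3-decimal precision and are
never re-derived. Unnamed compounds are addressed by variable label and
chromatographic coordinates, so `map_features_by_retention()` can map a
user's aligned table onto x₁..x₁₄ within ±2 s / ±0.2 s retention
windows (the alignment tolerances of the upstream software).
`evaluate_on_cohort()` applies the predictor to a standardized cohort
and feeds `residual_summary()`.

## Compound identification

`retention_index()` implements the van den Dool–Kratz linear retention
index on a C8–C20 alkane ladder (RI = 100·n at each rung), with linear
extrapolation (flagged) outside the ladder span. `polarity_percent()`
places an experimental RI between non-polar and polar reference indices;
values in the 5–35% window — reflecting a mid-polar first-dimension
stationary phase — count as confirmatory RI evidence.
`assign_id_level()` applies the MSI confidence tiers on the 0–1000
spectral-match scale: level 4 strictly below a match of 800 (exactly 800
is level-3 eligible; the published guideline wording overlaps at the
boundary and this package resolves it upward), level 3 at/above 800
without polarity-window evidence, level 2 with it, level 1 with an
analytical-standard verification on top. Agreement with a non-polar
reference RI within 6% supports retaining the library name at level 3
but does not promote a compound to level 2 — only the polarity-window
consistency does.

## Synthetic cohorts and what they do (and do not) show

`generate_cohort()` simulates the direction cortisol = f(VOCs) + ε
directly, so the regression target is well-specified and support
recovery is a meaningful acceptance surface. Per sample:

$$\log_{10}(\text{cortisol}) = \mu_{\text{tp}} \pm
\tfrac{1}{2}\delta_{\text{sex}} + u_{\text{subject}} +
\textstyle\sum_{j \in S}\beta_j z_j + \sum \gamma_{jk} z_j d_k +
\varepsilon,$$

with standardized log10 abundances $z$, planted support $S$ (default
14 of 512 features), diurnal means decreasing morning → evening
(defaults 0.80/0.50/0.30 log10 µg ≈ 6.3/3.2/2.0 µg per void), a sex
shift of 0.2 log10 units (detectable at the study's sample size, as the
original screen found), subject effects (SD 0.1) and noise (SD 0.2).
Defaults give a planted-signal to residual structure comparable to a
moderately predictive VOC panel. Design choices:

* **Missingness is left-censoring**, not missing-completely-at-random:
  per feature, the lowest `missing_rate` fraction of abundances is set
  missing, matching detection-limit physics and exercising the presence
  filter and half-minimum imputation realistically.
* **Outliers are planted**: a fraction of samples is re-assigned
  cortisol above the 45 µg ceiling so the outlier filter has known true
  positives. Non-outlier samples are kept below the ceiling by drawing
  the noise term from an upper-truncated normal — emulating a screened
  healthy cohort — so the filter's true-positive set is exactly the
  planted set and the 180 → 178 sample arithmetic of the study design
  is reproducible for any seed. With `noise_sd = 0` truncation is
  skipped, preserving the exact noiseless linear limit (in that limit
  the subject effect should also be set to 0, as it is an error
  component, not part of the planted fixed design).
* One integer seed governs all draws; identical configurations produce
  bit-identical cohorts.

The recovery experiments in the acceptance tests run at stated high-SNR
conditions: 60 subjects × 3 timepoints, 512 features, 14 planted main
effects with `effect_scale = 0.3` (standardized effects ≈ 0.12–0.48)
against noise and subject SDs of 0.05, no censoring or outliers, and the
healthy ceiling disabled — with a strong planted signal the ceiling
would otherwise truncate the response and break its linearity, which is
a property of the simulated screening, not of the selection method.
Interactions are omitted from the support-recovery cohorts because a
planted interaction can legitimately cancel a feature's marginal slope
(the published model itself contains such sign reversals), which would
make marginal-association recovery ill-posed; interaction recovery is
exercised separately through the stepwise search on denser designs. At
these conditions the planted support occupied the top-14 frequency ranks
in every pilot replicate; the acceptance threshold (support within the
top 25 in ≥ 90% of 20 replicates at 100 bootstrap iterations) leaves
headroom for seed-to-seed variation. Problem sizes in the routine test
suite are smaller (12–30 subjects, 10–80 features, 15–50 iterations),
chosen to keep the default run fast while still exercising every code
path.

What passing these tests does **not** show: real GC×GC-TOFMS tables have
correlated features (co-eluting and chemically related compounds),
batch/run-order drift, and heavier-tailed abundance distributions than
the independent log-normal features simulated here; the generator also
does not simulate chromatograms, spectra, or alignment errors. Recovery
on synthetic cohorts validates the statistical machinery, not instrument
performance.

## Numerical conventions and edge cases

* AICc requires n > k + 1 and positive RSS; a perfect fit (RSS = 0) is
  guarded by flooring RSS at machine epsilon for criterion purposes and
  reporting adjusted R² = 1 with p-values at the numerical floor.
* Rank-deficient designs are an error in `fit_ols()` (naming the
  collinear terms); during stepwise search a rank-deficient candidate
  move is skipped instead.
* Elastic-net convergence tolerance is 1e-7 or tighter on coefficient
  change; `lambda = 0` with full column rank returns the exact OLS
  solution.
* The stepwise tie-break (earlier label), the top-k tie-break
  (frequency, then |coefficient|, then index) and the single run seed
  make every pipeline artifact reproducible byte for byte apart from the
  manifest timestamp.
* CSV round trips write numerics at 17 significant digits, so a written
  cohort reads back bit-identically, with empty cells as the missing
  mask.

## Known limitations

* Post-selection inference is naive: p-values and CIs of the final model
  do not account for the selection path, matching the reporting
  convention of the workflow this package implements.
* The factor screen ignores within-subject correlation.
* Full-set standardization before resampling leaks mild information
  across splits (documented above).
* The published predictor is shipped at printed precision; predictions
  inherit that rounding.
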