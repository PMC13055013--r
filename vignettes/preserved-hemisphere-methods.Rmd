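---
title: "Methods: preserved-hemisphere morphometry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preserved-hemisphere morphometry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemimorph)
```

This vignette is the package's own account of its statistical
machinery: the models and their assumptions, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
the numerical choices, and the design decisions made where the design
was genuinely open. It states no empirical result that the test suite
does not itself compute.

## 1. The design and its data model

The study design this pipeline serves compares post-surgical pediatric
epilepsy patients with controls on the morphometry of the patients'
*preserved* hemisphere only. Because a patient contributes exactly one
hemisphere while a control contributes two, hemisphere is a
between-subject variable for patients but within-subject for controls;
the design is not factorially orthogonal, and every comparison is run
within one hemisphere: preserved-LH patients vs the controls' LH rows,
preserved-RH patients vs the controls' RH rows, and the two patient
groups against each other. Controls' two hemispheres enter as separate
analysis rows throughout.

The interchange object (`morpho_table`) is a long table keyed by
(participant, hemisphere, measure, region), with five measures —
cortical thickness `CxT` (mm), cortical surface area `CSA` (mm²),
cortical volume `CV` (mm³) over the 34 Desikan-Killiany parcels,
`subcortical_vol` (mm³) over nine structures, and `gross_vol` (mm³)
over {LV, GM, WM}. Raw values must be strictly positive; region names
are canonicalized (lowercase, no separators) with an alias map covering
the FreeSurfer stats dialect (`Left-Hippocampus`, `ctx-lh-bankssts`,
`Accumbens-area`, ...). Which aseg label stands in for "cerebellum" is
genuinely ambiguous in the field's tables; the reader exposes
`cerebellum_alias` with the cortex-only label as default, since that is
what hemisphere-wise segmentations usually provide.

ILAE seizure-outcome classes are binned 1–3 → "low" (better outcome),
4–6 → "high". Surgery descriptions are classified *resection* vs
*ablation* by text: descriptions containing "ablation" or "evacuation"
are non-resective. The published 32-patient roster contains one
hematoma-evacuation case which must be counted as non-resective for the
group tallies (7 + 2 ablation; 12 + 11 resection) to be internally
consistent; we follow those tallies.

Missing clinical fields (one patient has no recorded seizure-onset age)
stay missing; statistics drop them pairwise, which is why the onset-age
comparison carries 29 error degrees of freedom instead of 30.

## 2. Normalization

Per participant-hemisphere: CxT is left alone (standard guidance for
thickness); CSA is divided by the mean of that hemisphere's 34 parcel
areas; CV and subcortical volumes are divided by the total hemisphere
volume, subcortical additionally ×100 (a percentage). The total is
GM + WM + LV — the inclusion of LV follows the parenthetical definition
in the source description; the denominator is configurable
(`denominator =`) because GM + WM is a defensible alternative reading.
Hemispheres missing any gross volume are excluded (the denominator is
undefined); fewer than 34 CSA parcels is an error because the mean
parcel area would be biased.

A consequence worth knowing: normalization couples the gross volumes
into every ratio measure. A true GM deficit mechanically raises all
normalized CV and subcortical values of the affected group. This is a
property of the design, not a bug — it is why the pipeline includes a
gross-vs-regional correlation screen — and it is why the package's
end-to-end positive control injects its effect into CxT, the only
measure outside the denominator algebra.

## 3. Harmonization

Two-scanner cohorts need batch correction. We implement the standard
parametric empirical-Bayes location/scale model: per feature, OLS of
`y ~ scanner + group + age + gender` (scanner as one-hot indicators
under a zero-weighted-mean identifiability constraint), standardization
by the pooled residual SD, per-scanner location (γ̂) and scale (δ̂²)
estimates, method-of-moments hyperparameters across features (normal
prior for γ, inverse-gamma for δ²), and iterated conditional-posterior
updates to convergence (tolerance 1e-4 on the maximum absolute change,
cap 200 iterations, convergence failure is an error). Adjustment
restores the protected covariate structure:
`y* = σ/δ* (z − γ*) + α + Xβ`.

Numerical choices that differ from other implementations, and why:

- δ̂² uses the MLE (n) denominator rather than n−1, so the single-batch
  fit is an *exact* identity (the standardized residuals have unit MLE
  variance by construction); the acceptance suite asserts equality to
  1e-6.
- Degenerate priors are short-circuited: when the across-feature
  variance of δ̂² (or γ̂) is numerically zero, the raw estimates are
  kept instead of dividing by zero in the moment equations.
- The parametric variant only: the non-parametric EB weighting is out
  of scope.

Harmonization is fitted once on the full cohort (all measures' features
as columns) before any contrast splitting, with group protected so a
group/scanner confound is not absorbed into the batch term. We
harmonize *normalized* values; the order is a genuinely open choice and
is recorded in the run provenance.

Exact idempotence is not a property of this procedure: re-harmonizing
already-harmonized data re-estimates batch parameters from sampling
noise and the EB prior only partially shrinks them, so a second pass
moves values by a few percent of a feature SD at realistic n. The test
suite pins the attainable contract — bounded second-pass changes and
non-increasing residual scanner effects — rather than a fictitious
machine-precision identity.

## 4. Winsorization

Values below the 5th or above the 95th percentile estimate are replaced
by the estimate, per feature, independently within each cohort stratum
(preserved-LH patients, preserved-RH patients, controls-LH rows,
controls-RH rows). Nothing is ever dropped; record counts are
invariant. The percentile estimator is sorted linear interpolation
(quantile type 7) by default; the estimator is configurable because the
procedure is only "an approximation of the percentile values" by
construction. Note that type 7 is only *nearly* idempotent — a second
pass can move boundary values within one inter-order-statistic gap —
whereas order-statistic estimators (type 1) are exactly idempotent;
both properties are tested. Strata with fewer than three observations
pass through untouched.

Winsorizing within group strata slightly distorts exchangeability
between groups; this is inherited from the analysis design the package
implements and is visible only as a second-order effect in the
permutation calibration (which the acceptance suite measures on
un-winsorized nulls).

## 5. Univariate inference

Per feature, an OLS GLM with group as the predictor of interest and age
and gender (female = 0, male = 1) as covariates. Inference is by label
permutation: the group vector is shuffled uniformly (no
stratification), covariates stay fixed, and `p_raw` is the fraction of
shuffles whose |β| *strictly exceeds* the observed |β| — the literal
exceedance rule, which can return p = 0. A `pcount = "plus_one"` option
gives the (b+1)/(m+1) convention. Two guards make the rule total: exact
ties (e.g. the observed assignment re-appearing in an exhaustive
enumeration) are compared with a 1e-10 relative tolerance so
floating-point noise cannot decide them, and a response that is
constant after covariate projection returns p = 1. For small balanced
designs `exhaustive = TRUE` enumerates all `choose(n, n1)` assignments.

The implementation residualizes the response and all shuffled group
vectors on the nuisance design once (Frisch-Waugh-Lovell), so a
feature's 1,000 shuffles cost one matrix product. Each feature draws
its shuffles from its own seed, derived from the master seed and the
feature's global vocabulary index; results are therefore independent of
family composition and evaluation order.

One operating characteristic matters when interpreting family-level
results: under the strict exceedance rule P(p = 0) = 1/(m+1) per null
feature, and a zero always survives Benjamini-Hochberg. With m = 1000
and 34 regions a null family fires with probability ≈ 3.4% — close to
the nominal family rate — but reducing m inflates this roughly
linearly. Calibration tests must therefore run at the stated m = 1000.

BH adjustment is applied per measure family (34 cortical regions per
cortical measure; 9 subcortical; 3 gross — we apply it to the gross
family too, the conservative reading of "across the total number of
ROIs"). The Bayes factor compares the full against the no-group model
via the BIC approximation `BF01 = exp((BIC_full − BIC_null)/2)`, chosen
because it is deterministic and reproducible where the source analysis
does not name its BF tool; magnitudes will differ from a JZS/g-prior
BF, so the 0.33/3 evidence thresholds, not the raw magnitudes, are the
comparable quantity. Under this variant a standardized effect of 1
needs n ≈ 100 before BF01 < 0.33 becomes near-certain.

## 6. Multivariate classification

Forward binary logistic regression per feature family: at each step the
candidate with the smallest Rao score-test p-value enters if p < 0.05;
there is no removal step; ties break by vocabulary order. Candidates
that induce (quasi-)complete separation — diagnosed by pinned fitted
probabilities or IRLS non-convergence, not by raw coefficient size,
which is not scale-invariant — are skipped with a warning rather than
entered with divergent coefficients. The final model is refit and
summarized by Nagelkerke R²,
`r2 = (1 − exp(2(ll₀ − ll₁)/n)) / (1 − exp(2 ll₀/n))`,
with bands < 0.2 weak, 0.2–0.4 moderate, ≥ 0.4 strong; fits with
R² ≤ 0.25 are labeled "weak relationship — not interpreted" per the
reporting rule. Age and gender are *not* forced into these models (the
source models list only morphometric predictors); an empty selection is
reported as "no viable model". The ILAE outcome (high vs low) is fit on
patients only, pooling both patient groups' preserved hemispheres.

## 7. Cohort statistics

Two-group one-way ANOVA F (pairwise-complete, df2 = n−2 on non-missing
data), the pooled two-proportion z (which reproduces the printed gender
z statistics from the roster counts; the "df" conventionally attached
to z is metadata only), median and MAD (unscaled by default — the
1.4826 factor is a flag), and a Pearson screen of each gross volume
against all 111 regional features at the corrected threshold p < 0.0002
(taken as given; the family size behind it is not re-derived). Two
printed values are knowingly not reproduced from the roster: the ILAE z
(printed 1.29; pooled z on the binned counts gives 1.33 — the original
test is unnamed) and the age MADs (printed 1.7/3.7; neither raw nor
scaled MAD of the rounded printed ages matches, presumably because
unrounded ages were used). We implement the well-defined statistics and
document the gap rather than reverse-engineer.

## 8. The synthetic generator

`generate_cohort()` draws every feature from exactly the linear model
the harmonization assumes:
`y = α_r + age·b_age,r + male·b_gen,r + patient·β_r·m_h + γ_s σ_r + δ_s σ_r ε`,
with ε standard normal, γ in units of the feature's residual SD, δ a
multiplicative noise factor, and `m_h` a hemisphere asymmetry
multiplier (default LH = 0, RH = 1, so injected effects reproduce the
"preserved RH differs, preserved LH does not" scenario). Positivity is
enforced by resampling ε, not truncation, to avoid a point mass at a
clip boundary.

Defaults are the stated world: 13 preserved-RH / 19 preserved-LH
patients and 51 controls; two scanners with assignment probabilities
49/83 and 34/83 (the study's scanner shares); ages uniform on 7–22
years (the study's span; no distribution is stated); ablation and
ILAE-high fractions 7/19 (LH) and 2/13 (RH), matching the roster;
β_r = 0 (null) because no effect sizes are published — effects are
injected explicitly where tests need them. Feature scales resemble
single-hemisphere FreeSurfer output (thickness ~2.8 mm, parcel areas
~2400 mm², parcel volumes ~9000 mm³, subcortical ~4200 mm³, GM/WM/LV
~280/220/8 cm³) with residual SDs of 4–30%; the default scanner effect
is a modest γ = 0.6 SD, δ = 1.3 on the second scanner. All parameters
sit in an editable `feature_params` table.

What the generator does *not* emulate — and therefore what a green test
does not establish: spatial covariance between regions (features are
conditionally independent given the covariates), non-linear age
trajectories, heavy-tailed or skewed measurement error, lesion-extent
heterogeneity within patient groups, and any real association between
morphometry and ILAE outcome. Tests passing on this world certify the
statistical machinery, not neurobiological realism.

## 9. Reproducibility and orchestration

`run_study()` executes normalize → harmonize → winsorize → univariate
(3 contrasts × 5 families) → multivariate (the 3 group outcomes + ILAE,
× 5 families) → matching report → correlation screen, with per-cell
error isolation (a failing cell is recorded and skipped, others
proceed), separation warnings collected into the report, and a
provenance block (config, seed, stage order, package version,
timestamp). A `resection_only` subgroup filter reruns the design on
resection cases only (12 + 11 on the published roster). Everything is
deterministic given (input, config, seed). The CLI verbs mirror the R
API one-to-one.

## 10. Known limitations

- The BIC Bayes factor is one convention among several; magnitudes are
  not comparable to JZS-style BFs.
- The permutation test treats controls' two hemisphere rows as
  exchangeable units within their hemisphere's contrast; no
  within-control correlation is modeled (each contrast uses one row per
  control, so this matters only for cross-contrast comparisons).
- Harmonization assumes location/scale batch effects; scanner effects
  on covariance structure are untouched.
- Forward selection inherits the usual caveats of stepwise procedures;
  the package reports in-sample fit only, by design.
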