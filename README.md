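# hemimorph

Statistical pipeline for comparing regional brain morphometry between
post-surgical pediatric epilepsy patients and typically developing
controls, analyzing only the **preserved hemisphere** — the hemisphere
contralateral to a resection or laser ablation, the sole source of
patient morphometry in this design.

The package is aimed at neuroimaging statisticians working with
FreeSurfer-style tabular output (per-parcel cortical thickness, surface
area and volume; subcortical and gross hemisphere volumes) from
multi-scanner case-control cohorts, and at methodologists who want the
whole inferential chain testable on synthetic cohorts with known ground
truth.

## The analysis

For each participant-hemisphere the input is a 114-feature vector: 34
Desikan-Killiany cortical parcels × {CxT (mm), CSA (mm²), CV (mm³)},
9 subcortical volumes, and 3 gross volumes (lateral ventricle LV, gray
matter GM, white matter WM). The pipeline then applies, in order:

1. **Normalization** — CxT untouched; CSA divided by the hemisphere's
   mean parcel area; CV divided by total hemisphere volume
   (GM + WM + LV); subcortical volumes as a percentage of that total.
2. **Scanner harmonization** — an empirical-Bayes location/scale batch
   model (ComBat-style): per feature *r* and scanner *s*,
   `y = α_r + x'β_r + γ_sr + δ_sr ε`, with normal/inverse-gamma priors
   across features shrinking the per-scanner additive (γ) and
   multiplicative (δ) effects; group, age and gender are protected
   covariates.
3. **Stratified winsorization** — values outside the 5th–95th
   percentile are clipped to the percentile estimates, separately
   within each cohort stratum (patients by preserved hemisphere,
   controls by hemisphere), so no record is ever dropped.
4. **Univariate inference** — per feature, an OLS GLM
   `y ~ group + age + gender`; the group label is shuffled 1,000 times
   and the two-sided p-value is the fraction of shuffles whose |β|
   exceeds the observed |β|; Benjamini-Hochberg correction is applied
   per measure family; a BIC Bayes factor
   `BF01 = exp((BIC_full − BIC_null)/2)` adjudicates evidence
   (BF01 < 0.33 → alternative, BF01 > 3 → null).
5. **Multivariate classification** — forward binary logistic regression
   (Rao score entry test, p < 0.05 to enter, no removal) predicting
   group membership or binned ILAE seizure outcome from each feature
   family, summarized by Nagelkerke R² with strength bands
   (< 0.2 weak, 0.2–0.4 moderate, ≥ 0.4 strong; fits with R² ≤ 0.25 are
   reported as weak and not interpreted).
6. **Cohort statistics** — two-group ANOVA F, pooled two-proportion z,
   median/MAD matching reports, and a Pearson screen of gross-vs-regional
   correlations at a corrected p < 0.0002.

A synthetic-cohort generator (`generate_cohort()`) draws all 114
features from exactly the linear model the harmonization assumes, so
every stage is testable with known ground truth; the published
32-patient roster (`generate_table1_roster()`) drives the cohort-level
worked examples.

## Worked example

A two-scanner cohort of 13 preserved-RH patients, 19 preserved-LH
patients and 51 controls, with a true GM deficit of 1.5 residual SDs
injected in the preserved-RH patients only:

```r
library(hemimorph)

fp <- default_feature_params()
fp$beta[fp$measure == "gross_vol" & fp$region == "GM"] <- -27000  # mm³, ~1.5 SD
cfg    <- cohort_config(feature_params = fp, asym = c(LH = 0, RH = 1), seed = 7)
cohort <- generate_cohort(cfg)

tab   <- normalize_morphometry(cohort$table)
model <- fit_harmonization(tab)                  # EB scanner model
tab   <- winsorize_stratified(apply_harmonization(tab, model))

run_univariate_family(tab, "RHpat_vs_RHctrl", "gross_vol",
                      n_perm = 1000, seed = 7)
#>           contrast   measure region   beta p_raw  p_bh     bf01 evidence_label
#> 1: RHpat_vs_RHctrl gross_vol     LV  -1697 0.012 0.018 0.423666   inconclusive
#> 2: RHpat_vs_RHctrl gross_vol     GM -32780 0.000 0.000 0.000729    alternative
#> 3: RHpat_vs_RHctrl gross_vol     WM   3250 0.648 0.648 7.145409           null

run_multivariate(tab, "RHpat_vs_RHctrl", "gross_vol")
#> Forward logistic regression — RHpat_vs_RHctrl / gross_vol
#>   selected (entry order): GM
#>   entry p: 0.000945
#>   Nagelkerke r2 = 0.264 (moderate)
```

The injected GM deficit is recovered (β ≈ −33 cm³ against a true −27
cm³, permutation p = 0 out of 1,000 shuffles, BF01 ≪ 0.33), WM is a
clean null, and LV at p_bh = 0.018 with an inconclusive BF01 shows why
the pipeline pairs p-values with Bayes factors. The forward regression
selects GM alone with a moderate Nagelkerke R².

The matching statistics of the published roster reproduce the printed
values:

```r
cohort_match_report(generate_table1_roster())[1:5, ]
#>                         comparison  statistic    value df1 df2     p
#> 1       age_at_test RHpat vs LHpat    anova_F  1.13432   1  30 0.295
#> 2    age_at_surgery RHpat vs LHpat    anova_F  0.02861   1  30 0.867
#> 3 seizure_onset_age RHpat vs LHpat    anova_F  0.00745   1  29 0.932
#> 4            gender RHpat vs LHpat two_prop_z -0.65366  30  NA 0.513
#> 5         ilae_high RHpat vs LHpat two_prop_z -1.32592  30  NA 0.185
```

`run_study()` orchestrates the full design (three contrasts × five
feature families, univariate + multivariate, plus the resection-only
sensitivity rerun) and `render_summary()` prints the at-a-glance
markdown table. A command-line wrapper with `simulate`, `preprocess`,
`harmonize`, `analyze`, `classify`, `cohort-report`, `xcorr` and
`run-study` verbs lives in `inst/exec/hemimorph`.

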