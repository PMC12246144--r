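# evreject

Longitudinal extracellular-vesicle (EV) surface-antigen profiling for
noninvasive monitoring of acute cellular rejection (ACR) after heart
transplant.

## What this package is for

Heart-transplant recipients are surveilled by repeated endomyocardial
biopsy, graded 0 < 1A < 1B < 2 < 3A (ISHLT); grades 2–3A trigger a
change of immunosuppression. Circulating EVs carry surface antigens of
the immune cells driving rejection, measurable in plasma by bead-based
flow cytometry as median fluorescence intensities (MFI) — a candidate
blood-based alternative to biopsy. This package implements the full
analysis pipeline for a longitudinal cohort of per-visit MFI panels:

- **Normalization** — per-sample tetraspanin normalization
  `nMFI(m) = MFI(m) / mean(MFI(CD9), MFI(CD63), MFI(CD81))`, then the
  patient-specific grade-0 delta
  `Δ(m) = (nMFI(m) / median nMFI over the patient's own grade-0 visits − 1) × 100`,
  in *retrospective* (whole follow-up) and *causal* (only earlier
  visits; dynamically adaptive) modes.
- **Marker selection** — Kruskal–Wallis trend across ordered grade
  groups with Bonferroni control over the 37-antigen panel.
- **Single-marker diagnostics** — ROC with Youden cutoffs and bootstrap
  AUC CIs, odds ratios per 1% delta (therapy-adjusted variant),
  post-treatment decrease test.
- **Rejection model (rRF)** — a random-forest regressor of 10
  bootstrap-bagged CART trees, each capped at 10 internal splits, on the
  14 rejection-associated delta features; training folds are rebalanced
  (RO / SMOTE / SMOTE-ENN); the ensemble mean is a coefficient in
  [0, 1] read as the probability of grade 2–3A rejection. Validation is
  leave-one-patient-out with causal test deltas; transfer between
  capture protocols, learning curve and overfit gap included.
- **Evaluation** — confusion metrics, ROC/AUC, grade-stratified
  summaries, Bland–Altman inter-protocol agreement.
- **Synthetic cohort generator** — a tested replica of the study design
  (24 patients, 285 visits, grade quotas 181/80/10/14, median 28-day
  intervals, printed per-grade effect ranges, lognormal noise, paired
  protocol bias, post-treatment decay), so the pipeline runs end-to-end
  without patient data. See the methods vignette
  (`vignettes/ev-rejection-profiling.Rmd`) for every modelling choice.

## Worked example

```r
library(evreject)

cohort <- generate_cohort(default_config(), seed = 1)
cohort
#> ev_cohort: 24 patients, 285 visit rows (IMMUNO)

table(grade_group(cohort$grade))
#>   G0 G1AB G23A
#>  181   80   24

# patient-adaptive normalization and differential-marker selection
norm <- normalize_cohort(cohort, mode = "retrospective")
select_markers(cohort, normalized = norm)
#>  [1] "CD2"   "CD3"   "CD4"   "CD8"   "CD19"  "CD20"  "CD24"  "CD25"
#>  [9] "CD45"  "CD49e" "CD62P" "CD142" "CD209" "HLA-I"
```

Exactly the 14 markers that carry planted grade effects are flagged; the
other 23 panel antigens are null and stay unselected. The weakest
planted grade-3A effect is ×18.88, i.e. an expected +1788% delta; at
n = 14 grade-3A visits the replica's median is noisy
(`median(norm$delta_CD2[norm$grade == "3A"])` prints `2111.8` here) and
converges to +1788 on a 200-patient cohort — that convergence is an
acceptance check.

```r
lopo <- lopo_validate(cohort, rf_config(), seed = 1)
lopo
#> ev_lopo: 24 folds, mean accuracy 0.982, pooled accuracy 0.977, AUC 0.993
lopo$confusion
#> tp=21 fp=2 tn=187 fn=3
#> sens=0.875 spec=0.989 acc=0.977 ppv=0.913 npv=0.984
learning_curve(lopo)
#>        bin   n accuracy
#> 1   2-5 G0 106 1.000000
#> 2   6-9 G0 107 0.953271
#> 3 10-14 G0   0       NA
```

Each of the 24 folds trains on the other 23 patients and predicts the
held-out patient's visits from their causal deltas (only that patient's
*earlier* grade-0 visits define the reference — the adaptive mechanism).
The 213 predicted visits are those with an established baseline
(≥ 2 prior grade-0 visits). Performance is high because the generator's
planted effects are large and marker-independent; it is a check of the
pipeline, not a clinical claim.

The same stages run from the command line:

```sh
Rscript inst/cli/evreject.R simulate --out runs/sim --seed 1
Rscript inst/cli/evreject.R pipeline --cohort runs/sim/cohort_immuno.csv --out runs/out --seed 1
Rscript inst/cli/evreject.R transfer --cohort runs/sim/cohort_msp.csv --cohort-b runs/sim/cohort_immuno.csv --out runs/tr
```

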