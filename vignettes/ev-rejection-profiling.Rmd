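---
title: "Longitudinal EV surface-antigen profiling for rejection monitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal EV surface-antigen profiling for rejection monitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a heart transplant, acute cellular rejection (ACR) is surveilled by
repeated endomyocardial biopsy, graded on the ISHLT scale (0, 1A, 1B, 2,
3A). Grades 2-3A are the actionable endpoint: they trigger an adjustment
of the immunosuppressive regimen. A blood-based alternative profiles the
surface antigens of circulating extracellular vesicles (EVs) by
flow cytometry: immune-cell-derived EVs carry markers of the cellular
processes driving rejection (T-cell markers CD2/CD3/CD8, antigen-
presenting-cell markers such as CD209, and others), and their levels rise
with rejection severity.

`evreject` implements the analysis pipeline for such a study design: a
longitudinal cohort of transplant recipients, one blood sample per
scheduled visit immediately before biopsy, a 37-antigen panel measured
after antibody-based EV capture ("IMMUNO" protocol) and a 14-antigen
panel after membrane-sensing-peptide capture ("MSP" protocol), each with
the three pan-EV tetraspanins CD9, CD63, CD81. Because no per-visit
cohort of this shape is publicly deposited, the package includes a
first-class synthetic generator that replicates the study design, so
every stage is exercised and tested end-to-end.

## Normalization model

Two nested normalizations remove the dominant nuisance variation:

1. **Tetraspanin normalization (nMFI).** Every marker's median
   fluorescence intensity (MFI) is divided by the mean MFI of CD9, CD63
   and CD81 from the same sample. This cancels per-sample scale
   (instrument settings, capture efficiency, EV yield). nMFI is
   dimensionless and invariant to rescaling all of a sample's MFIs.

2. **Patient-specific grade-0 delta.** Each marker's nMFI is expressed
   as a percentage variation relative to the *median nMFI over that
   patient's own grade-0 visits*:
   `delta = (nMFI / ref - 1) * 100`. This absorbs inter-patient baseline
   differences, which are large for circulating EV subpopulations.

The reference is computed in two modes:

- **retrospective** - the median over all grade-0 visits of the
  follow-up. Used for cohort-level statistics (marker selection, ROC,
  odds ratios) and for model *training*, where the training patients'
  full follow-up is known.
- **causal** - at visit *t*, only grade-0 visits strictly before *t*
  qualify. This is the dynamically adaptive mechanism used at
  *prediction* time: with every new grade-0 visit the patient's
  reference, and hence the effective decision threshold, is refined.

The first post-transplant sample is excluded from reference pools in
both modes: surgery itself perturbs EV subpopulations (endothelial
damage, inflammation), so it is treated as its own time-point class. A
visit is **evaluable** for prediction once at least 2 prior grade-0
visits back its reference; requiring a minimal baseline is what the
learning-curve analysis (accuracy vs number of grade-0 episodes,
starting at the 2-5 bin) presupposes. Medians of even-sized pools are
the midpoint of the two central values.

Whether the cohort-level tables of the original analysis used the
retrospective or the causal reference is not decidable from the study's
description; both modes are exposed, with the assignment above
(retrospective for population statistics and training, causal for
prediction) as the default convention.

## Time-point classes

Each visit gets one of six mutually exclusive classes: `AFTER_SURGERY`
(visit 0), `G0`, `G1AB`, `G23A`, or the anticipatory classes `PRE_1AB` /
`PRE_23A` for the single visit immediately preceding a 1A/B or 2-3A
diagnosis. Precedence: a visit's own 2-3A diagnosis outranks pre-status;
`PRE_*` outranks `G0`/`G1AB` otherwise; `PRE_1AB` only applies to
grade-0 visits. The "pre" window is one scheduled visit, not all prior
visits - the anticipatory claim of the analysis is about the visit
before diagnosis, singular.

## Marker selection and single-marker diagnostics

- **Trend test:** Kruskal-Wallis across the four ordered grade groups
  (0, 1A/B, 2, 3A) on retrospective deltas. The original analysis names
  only "parametric and non-parametric tests, as appropriate"; a
  Jonckheere-Terpstra-style ordered alternative is available behind a
  flag, but the omnibus rank test is the default used for selection.
- **Multiplicity:** Bonferroni over the 37-marker panel, alpha 0.05.
  The original report is silent on multiplicity; conservative
  family-wise control is what makes a 14-of-37 recovery claim
  meaningful, and the suite verifies empirically that the family-wise
  error is controlled under a global-null generator.
- **ROC:** AUC by rank concordance (midrank ties); the cutoff maximizes
  Youden's J, with ties broken toward the higher cutoff (higher
  specificity under the ">= cutoff calls positive" rule). AUC CIs are
  stratified bootstrap percentiles, 2000 resamples, seeded.
- **Odds ratios:** logistic regression of the 2-3A endpoint on delta in
  percentage points ("per 1% increase"), Wald 95% CIs; the multivariate
  variant adds the immunosuppressive regimen (cyclosporine- vs
  tacrolimus-based) as a covariate. Complete separation is detected and
  flagged rather than reported as a finite estimate.
- **Treatment response:** each 2-3A visit is paired with the patient's
  first subsequent visit after the therapy adjustment, and the decrease
  is tested one-sided by Wilcoxon signed rank (the hypothesis is
  directional: treatment lowers the rejection-associated elevation).

## The rejection-probability model

A small random-forest *regressor* (rRF) on the 14 delta features:
10 bootstrap-bagged CART regression trees, each grown best-first with at
most 10 internal split nodes, leaf value = mean {0,1} label. The
ensemble mean is a coefficient in [0, 1] read as the probability of
grade 2-3A rejection; calls use threshold 0.5 (the original binarization
rule is unstated; the threshold is configurable and the full ROC is
reported so any operating point can be audited). "Maximum number of
splits equal to 10" is read as a cap on split *nodes* per tree (hence at
most 11 leaves), not tree depth - the phrasing names splits - and the cap
is configurable.

- **Class imbalance.** Grade 2-3A visits are <10% of the data. Training
  folds are rebalanced by random oversampling (RO, the configuration the
  study retained), SMOTE (synthetic points on segments between minority
  neighbours, k = 5), or SMOTE plus edited-nearest-neighbour cleaning.
  When the minority is smaller than k + 1, SMOTE falls back to RO with a
  warning so small cohorts remain runnable. Oversampling is applied
  strictly inside training folds.
- **Validation.** Leave-one-patient-out (LOPO): one fold per patient,
  trained on the other N-1 patients' retrospective deltas, tested on the
  held-out patient's causal deltas. Reported accuracy is the mean of
  per-fold accuracies; pooled confusion counts and pooled AUC are also
  computed. The suite verifies each fold's model is exactly reproducible
  from the other patients' data alone.
- **Grid search.** When enabled, hyperparameters (oversampler, tree
  count, split cap) are tuned by patient-grouped 5-fold cross-validation
  *inside each LOPO training set*, never on the full cohort - the
  original description ("a grid search technique was applied") does not
  say whether tuning was nested; nesting is the choice that cannot leak
  selection information. Ties break toward fewer trees, then fewer
  splits.
- **Transfer.** Models trained on one protocol's deltas are evaluated on
  the other's; the patient-specific delta normalization absorbs the
  multiplicative inter-protocol bias, which is what makes the transfer
  meaningful.

## The synthetic generator: what it emulates

The default configuration is the study replica, fixed once from the
stated design:

| quantity | default | source |
|---|---|---|
| patients | 24 | stated design |
| visits | 9-17 each, 285 total | stated design |
| visit interval | median 28 d (jitter 14-35 d) | stated design |
| grade quotas | 181 / 80 / 10 / 14 (G0, 1A+1B, 2, 3A) | stated design |
| 2-3A carriers | 14 patients, 3 with 3 episodes | stated design |
| grade effects | 1A/B x3.01-4.14; G2 x6.76-11.94; G3A x18.88-46.77 | printed delta ranges |
| pre-diagnosis effects | pre-1A/B x1.043-2.31; pre-2-3A x1.82-6.39 | printed delta ranges |
| measurement noise | lognormal, CV 0.25 | assay CV 5.8-20.7%, rounded up for biology |
| baseline spread | lognormal, CV 0.5 across patients | chosen: large inter-patient variability is the premise of patient-specific normalization |
| protocol bias | tetraspanin MFI x1.03; antigen nMFI x1.062 | printed overestimations |
| pairing noise | lognormal, CV 0.05 | lower end of the assay CV range |
| treatment decay | residual elevation x0.25 per visit | chosen: gives the reported post-treatment decrease |

Mechanics: each patient has a latent lognormal baseline nMFI per marker
(mean 0.5); observed antigen MFI is baseline x effect x decay x noise x
(that visit's mean tetraspanin MFI), so in the noiseless limit nMFI
equals the latent baseline exactly. Tetraspanins are drawn around a
common scale (5000) independently of grade - grade information enters
only through the 14 affected antigens, making nMFI the signal carrier.
The 23 remaining panel antigens carry multiplier 1 at every grade and
act as true negatives for selection.

Choices the stated design leaves open, decided once:

- **Per-marker effect spread.** Only per-grade ranges across markers are
  printed; multipliers are evenly spaced over each range in panel order,
  so the first panel marker (CD2) carries the weakest effect at every
  grade (x18.88 at grade 3A, i.e. +1788%).
- **Grade sequence layout.** Deterministic quota allocation: a leading
  grade-0 block (so every patient accrues a causal baseline before any
  episode), then a rejection tail in which each 2-3A episode is preceded
  by a 1A/B visit when available and leftover 1A/B visits follow the
  last episode. This also keeps post-treatment residual elevation (which
  decays x0.25 per visit) off grade-0 visits, so grade-0 reference pools
  are clean - without this, the printed effect sizes would not be
  recoverable from the generator that plants them.
- **Visit counts** are spread over 9-17 deterministically (longest
  follow-up for the multi-episode patients), and alternate inter-visit
  intervals are pinned at the 28-day median with the rest jittered
  uniformly on 14-35 d, which makes the overall median interval exactly
  28 by construction.
- **Protocol bias scale.** The antigen overestimation is defined on the
  nMFI scale (the scale on which it is reported); raw antigen MFI in the
  derived MSP rows therefore carries both the antigen and the
  tetraspanin factor (1.062 x 1.03).

What the generator does **not** emulate: biochemical covariates,
antibody-mediated rejection biology (the AMR flag exists only so the
exclusion filter is exercised), spectral spillover, batch effects,
missing visits, or any correlation structure among markers beyond the
shared tetraspanin denominator. A green end-to-end test therefore
establishes that the pipeline correctly recovers the structure this
world states - planted effects, biases, quotas - not that the model would
achieve any particular performance on real patients; the headline
accuracies of the original study are statements about undeposited data
and are deliberately not reproduction targets.

## Numerical and reporting choices

- All randomness flows from explicit integer seeds; the pipeline's
  top-level seed expands deterministically into per-stage seeds recorded
  in the run manifest, so any stage can be re-run in isolation.
- Cohort CSVs are written with 17 significant digits; read-write
  round-trips are bit-exact.
- Bland-Altman agreement uses the percentage-difference scale
  `100*(msp - immuno)/mean(pair)` (the bias is reported as a percentage
  overestimation). An exact ratio r maps to `200(r-1)/(r+1)` on this
  scale (6.02% at r = 1.062); the reported `overestimation_pct`
  back-converts the mean bias via `r = (200 + d)/(200 - d)`. Under
  multiplicative pairing noise the mean of the per-pair differences
  contracts slightly below the noiseless value (the transform is
  concave), and the 14 antigen pairs of one visit share a tetraspanin
  denominator, so interval checks of the recovered bias resample whole
  visits, the independent unit. The "quadratic R" agreement coefficient
  is the multiple correlation of a second-degree polynomial fit, the
  linear one is Pearson's r.
- Undefined confusion ratios (e.g. PPV with no positive calls) are
  reported as flagged missing values, never coerced to 0. Printed
  predictive values inconsistent with printed counts are never copied;
  all metrics derive from counts.
- Exclusions: only AMR-flagged visits are removed (not the whole
  patient), series are re-indexed, and the filter is idempotent.

## Limitations

The generator's marker effects are independent across markers given the
grade, which makes multivariate selection easier than on real data where
immune markers co-vary; the learning-curve upper bin (10-14 grade-0
episodes) is empty in the 24-patient replica because no patient
accumulates more than 10 grade-0 visits; and SMOTE-ENN cleaning can
leave classes slightly unequal by design. The package analyzes MFI
tables - instrument files (FCS), compensation and gating are upstream
and out of scope.
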