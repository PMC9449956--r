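---
title: "Classifying facial-palsy severity from facial animation units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying facial-palsy severity from facial animation units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faupalsy)
```

## The model

Unilateral facial paralysis weakens the voluntary musculature of one side
of the face. During a facial movement, the paralyzed side's animation
units activate less than the healthy side's, and less than they would at
the same severity on a milder grade. Two feature families capture this:

* **Animation symmetry indices (ASIs).** For each of the six left/right
  FAU pairs and each movement, `ASI = |FAU_left − FAU_right|`. A healthy
  face is near-symmetric (ASI ≈ 0); asymmetry grows with severity. The
  side of the lesion is carried by the *grades*, not the ASIs (which are
  symmetric in L/R by construction).
* **Facial-function grades.** For each movement's most-affected FAUs, the
  signed difference between the movement frame and the rest frame. A
  paralyzed side produces small grades on its FAUs; the healthy side
  produces large ones. Signs are kept because the direction of activation
  is informative.

Per session this yields 30 classifier ASIs (the 6 rest-state ASIs are
excluded — rest asymmetry is near zero for every class and carries no
discriminative signal), plus 11 grades: 41 features, partitioned into
per-movement subsets of sizes 8, 8, 8, 8 and 9 (whistling contributes
three grades, including the midline lip pucker FAU14).

The classifier is a two-level ensemble. Five RBF-kernel SVMs are trained
in parallel, one per voluntary movement, each seeing only its own
subset — the bagging-flavoured half. Their predictions are fused by a
rule-based combiner — the stacking-flavoured half:

1. a strict majority (≥ 3 of 5 votes) wins;
2. a unique class with 2 votes wins;
3. in a 2–2 tie involving the normal class, the non-normal class wins;
   in a 2–2 tie between two palsy classes, the one with the larger
   probability mass summed across the five classifiers wins;
4. if all five votes differ, the class with the highest summed
   probability wins.

Rules 3–4 are this package's own resolution of the tie cases, biased
against the normal class for the same reason as threshold moving (below);
every prediction records which branch fired (`rationale`), so combiner
behaviour is auditable. Residual ties are broken by the canonical class
order, making the combiner deterministic and invariant to classifier
ordering.

## Imbalance strategy

Clinical FP cohorts are dominated by healthy controls. Three techniques
are combined:

* **Random undersampling** of the normal class (default target 289
  records, giving a 664-record design with the published class
  frequencies).
* **SMOTE** with k = 5 neighbors (the canonical default) brings every
  class up to the majority count. Synthetic rows are flagged in a
  `provenance` column and are convex combinations of same-class
  originals, so label purity holds by construction.
* **Threshold moving** at prediction time: the class-probability argmax
  is overridden only when the normal class wins with probability below
  0.4, in which case the second-ranked class is returned. This demotes
  weak "normal" wins, which under imbalance are the most common error
  mode. By default the rule is applied to each first-level classifier
  before voting; `threshold_level = "ensemble"` applies it only to the
  fused decision.

SMOTE is applied to the training part *after* the stratified split by
default, so no synthetic sample can leak into evaluation data. The
alternative ordering (augment, then split) is available via
`augment_before_split` in `pipeline_config()` because protocols in the
literature are frequently ambiguous on this point; see *Robustness*
below.

## Tuning and numerical choices

* **Grid search.** Exhaustive (C, γ) search by stratified 5-fold CV mean
  accuracy, full ranges C ∈ 10^−3..10^8 (12 values) and γ ∈ 10^−3..10^3
  (7 values), 84 cells. Ties are broken toward the smallest C, then the
  smallest γ — preferring the least-complex model among equals — which
  also makes the search invariant to cell evaluation order. The pipeline
  default is a 4 × 4 subgrid (C ∈ {0.1, 10, 10³, 10⁵}, γ ∈ {0.01, 0.1,
  1, 10}) spanning the region where RBF-SVMs on standardized features of
  this dimensionality actually select; the full grid remains available
  through `C_grid` / `gamma_grid`.
* **Scaling.** SVM and K-NN features are standardized with
  training-partition statistics (zero-variance columns are centered
  only); random forests are fit unscaled. RBF kernels on mixed-scale
  features require this even though ASIs and grades are nominally on
  comparable [0, 1]-ish scales.
* **Probabilities.** Class probabilities come from libsvm's pairwise
  coupling with Platt-type calibration (`e1071`). The calibration step
  consumes the R RNG, so every fit runs under a locally set seed;
  refitting with the same data, parameters and seed is bit-reproducible.
* **Display rounding.** Percent metrics are reported to one decimal,
  rounded half away from zero; internal values keep full precision.
  Zero-denominator metrics are reported as `NA` and flagged, never
  coerced to 0 or 100.
* **Stratified split.** The test allocation rounds down per class and
  assigns the remainder by largest fractional remainder, keeping both
  parts within one sample of the global class proportions (a 664-record
  design at ratio 0.8 gives a test set of 132–133).

## The synthetic cohort generator

Real FAU recordings of FP patients are not publicly deposited, so the
generator defines the study conditions for all tests. Each movement has
a baseline activation template (primary paired FAUs at 0.8, whistling's
midline FAU14 at 0.7 and cheek FAUs at 0.5, small co-activations of
mechanically coupled pairs, rest at 0). For a record with side *s* and
severity *v*, every paired FAU on side *s* that the movement activates
is multiplied by the attenuation factor (1.0, 0.65, 0.35, 0.10 for none,
mild, moderate, severe — an evenly-spread ladder on [0, 1] chosen once
as a plausible severity progression). The midline FAU14 is attenuated by
`(1 + a) / 2`, since both sides contribute to the pucker and only one is
weak. Gaussian noise (default sd 0.05, roughly 6% of a full activation)
is added, and values are clipped to [0, 1]. Default class counts are the
published frequencies (289 normal after undersampling, 127 / 0 / 0 / 35
/ 177 / 36 for the palsy classes).

The generator emulates the *geometry* the classifier assumes —
side-specific, severity-graded attenuation with independent sensor
noise. It does **not** emulate several properties of real data:
correlated noise across FAUs, within-patient correlation between repeated
sessions, severity heterogeneity within a clinical grade, compensatory
contralateral hyperactivation, or covariates such as age and chronicity.
Passing tests therefore demonstrate that the pipeline recovers the
intended structure when present, not that published real-data accuracy
transfers to new cohorts.

## Robustness protocol

`cv_robustness()` repeats stratified 5-fold CV with different splits
(default 5 repetitions) per movement classifier, with and without SMOTE,
and reports mean ± SD of pooled accuracy and macro precision,
sensitivity and F1. Two augmentation placements are supported:

* `augment_before_folding = FALSE` (default): SMOTE inside the training
  folds only. Validation folds contain no synthetic samples. Under this
  leakage-safe protocol, augmentation changes pooled CV accuracy only
  marginally on the synthetic cohorts — balancing shifts errors between
  majority and minority classes rather than removing them.
* `augment_before_folding = TRUE`: SMOTE on the whole dataset before
  fold assignment, so validation folds are balanced and contain
  synthetic samples. Under this protocol augmentation raises mean CV
  accuracy substantially and shrinks its spread, the pattern commonly
  reported for SMOTE-augmented CV. The acceptance checks exercise this
  protocol because it is the one whose qualitative signature (higher
  mean, lower SD with augmentation) is well-defined on these cohorts; the
  leakage-safe numbers are the ones to trust for generalization claims.

## Problem sizes used by the checks

The test suite and the acceptance script generate all data in code.
Study-scale checks use the 664-record design (published class
frequencies); the parameter-recovery check runs the full pipeline on five
seeded cohorts at noise sd 0.05 with the default attenuation ladder and
the 4 × 4 tuning subgrid, requiring held-out macro-F1 ≥ 0.85 in at least
4 of 5 seeds. The robustness check uses a deliberately imbalanced, noisy
cohort (187 records, minority classes of 6, noise sd 0.15, chosen to
stress the imbalance machinery) with 5 repetitions of 5-fold CV.

## Known limitations

* The ASI definition used here is the simplest one consistent with
  left-right comparison (`|L − R|`; a normalized variant is available via
  `normalize = TRUE`). Selected SVM hyperparameters depend on the ASI
  scale, so they need not match values tuned on other ASI formulations.
* Two of the seven classes (left moderate, left severe) default to zero
  records, mirroring the published cohort; the class machinery supports
  them whenever counts are supplied.
* The K-NN baseline reports only the winning neighbor proportion as its
  probability; the remainder is spread uniformly. This is sufficient for
  accuracy sweeps but crude for probability-sensitive use.
* Each record is treated as an independent session; real repeated
  recordings of one patient violate this, and cross-validation on such
  data would need grouped folds.
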