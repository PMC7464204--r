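---
title: "Cross-cohort signature projection: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort signature projection: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresig)
```

## The model

`coresig` is built around a two-class compound covariate classifier. Given
gene-wise standardized expression (z-scores) and a binary training labeling,
each signature gene receives a pooled-variance Student t-statistic as its
weight, and each sample the weighted sum of its expression over the
signature — the compound covariate score. The two training classes induce
Gaussian distributions on this score (per-class mean and sample SD), and a
new sample's score is converted to a posterior probability of the positive
class by Bayes' rule with configurable priors (equal by default). A sample
is called positive when the posterior strictly exceeds the cutoff; a
posterior exactly at the cutoff yields the negative call, because the
positive class is the flagged condition and should require strict evidence.

The classifier is deliberately simple: a single linear score with a
one-dimensional Gaussian class model. Its strength for signature projection
is that nothing except the gene weights and four score-distribution
parameters crosses the platform boundary, and gene-wise standardization on
each side removes platform location/scale differences. When the two class
SDs are equal the posterior reduces to a logistic function of the score —
the closed form the test suite uses as an independent oracle.

### Core-signature derivation

The derivation runs in three steps per training cohort: (1) the cohort's
*original* signature — a labeled reference expression panel — is
standardized, a classifier is trained on it, and the cohort's own samples
are stratified at the 0.5 posterior cutoff; (2) genes differentially
expressed between the two predicted subgroups are selected with a pooled
two-sided t-test at `p < 0.001` together with at least a two-fold mean
difference; (3) the per-cohort gene lists are intersected. Genes surviving
the intersection moved consistently in every cohort, which is exactly the
cross-cancer reproducibility the core signature is meant to capture.

Fold change is computed as a difference of means on log2 expression
(`|Δlog2| ≥ 1` ⇔ two-fold), on *unstandardized* values — fold change is
meaningless on z-scores — and the two-fold boundary is inclusive. No
multiple-testing correction is applied: the derivation uses raw p-value
cutoffs, and the cross-cohort intersection itself acts as the stringency
filter. The Student (pooled) test is the default; Welch is available via
`var_equal = FALSE`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p_cut` | 0.001 | raw two-sided p-value cutoff for DE selection |
| `fold_cut` | 2 | minimum fold change (linear scale), inclusive |
| `cutoff` | 0.5 | posterior probability cutoff for all calls |
| `min_coverage` | 0.5 | minimum fraction of signature genes present before a projection is attempted |
| `priors` | 0.5 / 0.5 | class priors of the Bayes rule |

Coverage matters because signatures are projected across platforms: genes
missing from the target (or dropped as zero-variance during
standardization) are silently excluded and the realized coverage is always
reported; below `min_coverage` the projection errors out rather than
returning a silently degraded call.

Standardization is performed **within each cohort independently** (training
panel and target separately). Joint standardization would leak target
composition into the training geometry; separate standardization matches
the projection setting where the target cohort arrives after the signature
is fixed. Leave-one-out cross-validation refits the weights and score
densities without the held-out sample but keeps the gene set fixed, since
the signature is derived externally to the training panel; LOOCV is
reported as a robustness estimate whenever both classes have at least three
samples.

## The synthetic study generator

`simulate_study()` fabricates the full multi-cohort inputs: per-cohort
log2-scale expression with two latent classes, a labeled reference panel
per cohort, survival and subtype annotations, and sidecar ground truth.
Expression is Gaussian on the log2 scale — per-gene baseline means drawn
once per study from N(8, 2), per-gene noise SD 1.0 — rather than
negative-binomial counts, because every pipeline stage operates on
log-scale continuous values; count-level realism would add nothing the
pipeline can see. The default scale (4 cohorts × 120 samples × 5,000 genes,
60 shared and 40 cohort-specific DE genes at Δlog2 = 1.5, reference panels
of 30 samples per class) keeps a full derivation in a few seconds while the
planted effects sit comfortably above the detection thresholds; the tests
and the acceptance script run at this scale.

Design choices worth making explicit:

* **Coherent DE signs.** Each DE gene's direction is drawn once per study
  (P(up) = 0.8) and shared by all cohorts, so "shared" genes shift the same
  way everywhere — mirroring the empirical observation that core-signature
  genes are predominantly upregulated in the positive subgroup.
* **EMT coupling.** A disjoint 64-gene EMT-like program is shifted upward
  by 1.0 log2 units in positive-class samples of every cohort. This plants
  the positive-class ↔ mesenchymal association the downstream correlation
  statistics are meant to detect. Because the shift sits exactly at the
  two-fold boundary, EMT genes enter DE lists stochastically — a useful
  stress on the intersection logic.
* **Survival.** Event times are exponential with baseline hazard ln2/15
  per month (median 15 months in the negative class, a realistic
  glioblastoma scale), hazard ratio 3 for the positive class, and uniform
  censoring on (0, 60] months. Subtype labels are drawn with mesenchymal
  enriched (0.7 vs 0.1) in the positive class for chi-square association
  tests.
* **Determinism.** All substreams derive from `(seed, cohort_index,
  purpose)`, so a single cohort can be regenerated without the rest of the
  study and a rerun with the same seed is byte-identical.

What the generator does **not** emulate: gene–gene correlation beyond the
planted class structure, platform/batch effects, probe-level artifacts,
count overdispersion, or non-proportional hazards. Passing tests on this
generator therefore demonstrate the pipeline's statistical correctness on
its assumed data model, not robustness to the full messiness of real
cross-platform cohorts.

## Numerical choices

* Posteriors are computed in log space (difference of log densities through
  a logistic), which is stable over the whole score range; at extreme
  scores the posterior still saturates to exactly 0 or 1 in double
  precision.
* Standardization uses the sample SD (n − 1). Zero-variance genes are
  dropped (and reported) rather than raising an error, since flat rows are
  routine in cross-platform matrices.
* Zero pooled variance in a t-test yields `t = 0, p = 1` with a flag,
  keeping the output table complete.
* Kaplan–Meier and the log-rank test delegate to the `survival` package
  (events-first at tied times, hypergeometric variance, no continuity
  correction), and the chi-square test is the uncorrected Pearson form —
  each verified in the tests against independently hand-coded oracles.
* Duplicate gene rows collapse by per-sample mean (order-invariant);
  missing cells are imputed with the gene's row mean below 20% missingness,
  otherwise the gene is dropped — keeping matrices dense, which the
  compound score requires.

## Open interpretation points

The immune-signature score is modeled as a BCCP posterior over a labeled
reference panel dichotomized at 0.5 — an interpretation, since only the
cutoff behavior of the original score is documented; the same machinery
serves the TGF-β-style activity signature with caller-supplied labels
(`score_probability_signature()`). Cross-cohort gene matching is by exact
uppercased symbol; probe-to-gene mapping for array platforms is out of
scope. The variance treatment of the score densities (per-class sample SD)
and the equal priors are configuration defaults, not uniquely determined by
the published description of the method's lineage.

## Problem sizes used in validation

The packaged checks run the default study (4 × 120 × 5,000) for derivation
and recovery, a 2-cohort study (1,000 genes, 100-gene signature, 100-sample
panel and target) for classifier generalization and LOOCV, 20,000 genes at
n = 50 + 50 for t-test calibration, 2,000 replicates at n = 100 per group
for log-rank type-I error, and n = 200 for the coupled
posterior–EMT–survival contrast. These sizes were chosen so the planted
effects match the configured conditions while a full run stays in the tens
of seconds.
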