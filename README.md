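# coresig

Cross-cohort gene-expression signature projection with a Bayesian compound
covariate predictor (BCCP).

## The problem

Transcriptional programs such as silencing of the Hippo pathway (with
consequent YAP1/TAZ activation) leave a reproducible expression footprint
across tumor types. A signature trained in one cancer can be projected onto
another — but only the genes that move *consistently across cohorts* are
trustworthy. `coresig` implements the full workflow for deriving and using
such a "core" signature:

1. **Stratify** each training cohort into positive/negative subgroups (e.g.
   silenced vs active pathway) by applying that cohort's original signature
   with a BCCP classifier;
2. **Select** differentially expressed genes per cohort with a pooled
   Student *t*-test (`p < 0.001`) and at least a two-fold mean difference on
   the log2 scale;
3. **Intersect** the per-cohort DE lists: genes common to every cohort form
   the core signature, which is then trained and projected onto new cohorts,
   again with a 0.5 posterior cutoff.

Downstream, the package scores samples by metagene averages (e.g. an EMT
score) or BCCP-style probability signatures (immune / pathway-activity
scores), and ties subgroup calls to outcome with Kaplan–Meier curves,
log-rank tests, chi-square association tests and Pearson correlation.

## The classifier

For signature gene *g* with class means *m₊,g*, *m₋,g* and pooled SD *s_g*,
the weight is the Student t-statistic

  t_g = (m₊,g − m₋,g) / (s_g · √(1/n₊ + 1/n₋))

computed on gene-wise standardized (z-score) expression. Each sample *j*
receives a compound covariate score c_j = Σ_g t_g·x_gj. Gaussian densities
N(μ₊, σ₊), N(μ₋, σ₋) fitted to the training scores give, via Bayes' rule with
equal priors,

  P(+ | c) = π₊·N(c; μ₊, σ₊) / [π₊·N(c; μ₊, σ₊) + π₋·N(c; μ₋, σ₋)]

and a sample is called positive when this posterior strictly exceeds the
cutoff (default 0.5). Classifier robustness is reported as the leave-one-out
cross-validated misclassification rate.

Because the real multi-cancer cohorts are external, the package ships a
synthetic multi-cohort study generator (`simulate_study()`) with planted
shared / cohort-specific DE genes, labeled reference panels, an EMT-like
program coupled to the positive class, and exponential survival with a class
hazard ratio — so the whole pipeline is testable end-to-end on known ground
truth.

## Worked example

```r
library(coresig)

cfg   <- study_config(seed = 42)       # 4 cohorts x 120 samples x 5,000 genes
study <- simulate_study(cfg)

# three-step core-signature derivation across the 4 cohorts
core <- derive_core_signature(study$cohorts, study$references)
core
#> Core signature: 60 genes common to 4 source lists
#>   source list sizes: cohort1=133, cohort2=130, cohort3=133, cohort4=130
#>   genes: G00272, G00315, G00364, G00748, G00768, G00871, G00883, G00959, ...

# project the core signature onto a target cohort
proj <- classify_cohort(core, study$references$cohort1, study$cohorts$cohort2)
proj
#> Signature projection: 60-gene signature, coverage 96.7%
#>  AH SOH
#>  53  67
#> training LOOCV misclassification rate: 0.000

# survival contrast between the predicted subgroups
co  <- study$cohorts$cohort2
lab <- proj$calls$label[match(co$clinical$sample_id, proj$calls$sample_id)]
logrank_test(co$clinical$os_time, co$clinical$os_event, lab)
#> Log-rank test: chi-square = 18.9179, df = 1, p = 1.365e-05
#>             AH   SOH
#> observed 39.00 52.00
#> expected 57.83 33.17

# EMT metagene score vs classifier posterior
emt <- metagene_score(standardize_genes(co$expression), study$truth$emt)
pearson_correlation(proj$calls$posterior, emt$score)
#> 0.970
```

The derivation recovers the 60-gene core planted by the generator (the
per-cohort lists also contain cohort-specific and EMT genes, which the
intersection and the reference panel prune away — hence 96.7% coverage).
The predicted positive subgroup shows significantly worse survival (its
hazard ratio is 3 by construction) and its posterior correlates strongly
with the EMT metagene score, reproducing the qualitative
signature → mesenchymal phenotype → poor-survival structure on known truth.

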