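---
title: "Methods: speech-acoustic prediction of CSF amyloid status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech-acoustic prediction of CSF amyloid status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amyvoice)
```

## The scientific setting

In memory-clinic patients with mild cognitive impairment (MCI), brain
amyloid-β pathology is established by lumbar puncture: CSF Aβ1-42 below
a clinic-calibrated cutoff of 796 pg/mL is read as amyloid *positive*
(the comparison is strict: 796.0 itself is negative). The package
models the question of whether that binary status can be predicted
non-invasively from 88 eGeMAPS v02 acoustic functionals of a short
spontaneous-speech recording, in a cohort of about 52 MCI patients with
30 positives (57.7% prevalence), and whether acoustics outperform the
13-test neuropsychological battery plus demographics (age, sex,
education) that clinics already collect.

## The synthetic world

No clinical data ship with the package. `generate_cohort()` draws from
an explicitly stated generative world whose defaults are fixed once:

* **Group structure.** Exactly `n_positive = 30` of `n_subjects = 52`
  positive.
* **Demographics and neuropsychology.** Independent truncated
  Gaussians per group with the published group means/SDs (e.g. age
  76.8 (4.5) vs 69.4 (10.6); WAIS-III similarities 7.8 (2.8) vs
  10.8 (3.0)); sex as per-group Bernoulli (63.3% vs 68.2% female).
  Truncation bounds are each test's plausible range (scores ≥ 0, MMSE
  ≤ 30, ...). Inter-test correlation is not modeled: scores relate to
  each other only through the group label. This is a deliberate
  simplification — real batteries are strongly positively correlated —
  so a green test on the neuropsychological feature set establishes
  pipeline correctness, not clinical realism of that set's joint
  distribution.
* **Aβ1-42.** Truncated Gaussians per group (positive 600 ± 100
  truncated below 796; negative 1100 ± 250 truncated at/above 796).
  Only the cutoff is published; the group means are invented,
  configurable defaults chosen to sit clearly on either side of it.
  Truncation guarantees the label/biomarker consistency invariant.
* **Acoustics.** An 88-column multivariate Gaussian with unit
  variances and equicorrelation ρ = 0.3 (one shared factor:
  `X = sqrt(ρ) z + sqrt(1-ρ) ε`), with a standardized mean shift of
  `effect_size = 0.8` split ±0.4 around zero on 7 informative columns
  — the seven features reported as the strongest discriminators (F3
  bandwidth CoV, F2 bandwidth mean, unvoiced Hammarberg index, H1-A3,
  voiced spectral-flux CoV, voiced-segment-length mean and SD). An
  effect of 0.8 SD is what a t-test at n = 52 detects with moderate
  power, matching a world where univariate contrasts find only a
  handful of significant features but a multivariate classifier does
  clearly better than chance. Real eGeMAPS features have heavy tails,
  block-structured (not exchangeable) correlation, and
  non-multiplicative group effects; none of that is emulated.

All sampling is driven by one integer seed; equal seeds give
bit-identical cohorts.

## Group contrasts

`pooled_t()` is the equal-variance two-sample t (absolute value,
df = n₁+n₂−2), which reproduces the published statistic for the
similarities row (3.70) exactly; Welch is available behind a flag but
is not the default because the printed values match the pooled form.
`chi2_corrected()` is the Yates-corrected χ², floored at zero when
|ad−bc| ≤ n/2 — the floor is what makes the sex row print 0.00.
`adjusted_logistic()` fits by IRLS (tolerance 1e-8 on the largest
coefficient change, 100 iterations) and reports Wald p-values; perfect
separation is detected as a coefficient diverging past 15 on the
standardized scale and returned as a flag, never as a number. No
multiple-testing correction is applied anywhere, matching the
descriptive use of these tables.

## The swarm selector

`vlpso_run()` implements variable-length particle swarm optimization
as a wrapper selector:

* Features are ranked once, on the data handed to the selector, by
  symmetric uncertainty `SU = 2 I(X;Y)/(H(X)+H(Y))` with 10
  equal-frequency bins (features with ≤ 10 distinct values are used
  as-is). Constant features get SU = 0; ties break to the lower column
  index. Ranking once (not per fold) treats the ranking as part of the
  selector, which is the wrapper's own search bias, not an evaluation
  leak — the evaluation stage never sees held-out labels.
* Particle lengths span `ceiling(d·p/8)` for divisions d = 1..8;
  positions in [0,1] decode to subsets by strict thresholding at
  θ = 0.6; fitness is `subset_fitness()`: 1 − balanced accuracy of
  5-NN under seeded stratified 10-fold CV with training-fold
  z-scoring. Balanced accuracy guards against the 30/22 imbalance.
  The empty subset scores 1 by convention.
* Velocities follow per-dimension comprehensive-learning exemplars
  (tournament of two peers' personal bests, learning probability
  increasing across the swarm), inertia decays 0.9 → 0.4,
  acceleration 1.49445, velocity clamped at ±0.6, positions clamped
  (not reflected) at the bounds. Exemplars are reassigned after 7
  non-improving evaluations; after 3 stagnant global-best iterations
  the maximum length is renewed to the best-average-fitness division's
  length, longer particles truncate and their personal bests are
  re-evaluated. Fitness ties break toward fewer features, then earlier
  discovery, so the global-best trace is non-increasing by
  construction and the evaluation count satisfies
  `pop·(iters+1) + re-evaluations` exactly.

The swarm hyperparameters are documented defaults from the
comprehensive-learning/variable-length PSO literature (the source
study defers its exact values to a supplement that is not public);
every one is exposed in `swarm_config()`.

KNN tie rules are fixed for reproducibility: equal distances break to
the smaller training-row index, an even vote classifies positive.

## Models and evaluation

All families z-score columns with training statistics; PCA families
project onto the leading 9 components of the standardized training
data. The elastic net is penalized logistic regression (mixing 0.5,
penalty by seeded 5-fold CV over a 20-point logarithmic grid — the
source grids are unpublished, so the grid is configurable). The random
forest is bagged CART with per-node √p feature subsampling (500 trees),
implemented in-package because no forest library ships with this
stack. The SVM is a kernelized Pegasos solver (RBF width 1/p on the
standardized scale) whose decision values are mapped to probabilities
by a one-dimensional logistic calibration on the training data —
ranked scores are required for AUC. The hard-label threshold is fixed
at 0.5; no threshold tuning is described in the source and none is
performed.

`bootstrap_loocv()` nests a with-replacement resample of the training
fold *inside* each leave-one-out split: iteration b refits on a
resample of size n−1 (redrawn until both classes are present, redraws
counted) for every held-out subject, pools the n predictions into one
metric vector, and the B vectors form the metric distribution
summarized by its mean and 2.5/97.5 percentiles. This reading — one
metric vector per bootstrap pass, distribution across passes — is the
one consistent with an evaluation scheme described as "bootstrapping
the training set with LOOCV"; the alternative (bootstrap outside a
full LOOCV) is noted and not implemented. AUC is computed on pooled
held-out scores (per-fold AUC is undefined when folds hold one
subject) as the Mann-Whitney statistic with midranks. A test hook
(`resample_fn`) forces the identity resample, collapsing the scheme to
plain LOOCV exactly — this is asserted bit-for-bit in the tests.

Feature selection runs once on the full dataset before evaluation,
mirroring the single selected subsets that motivated the design and
keeping 5000 iterations tractable; this is optimistically biased for
the selection step, and a fully nested mode
(`run_study(..., nested_selection = TRUE)`, LOOCV only) exists with a
documented warning.

## Explanation

`exact_shap()` enumerates all 2^M coalitions (guard at M = 20) with
the interventional value function: v(S) is the mean model score over
the background rows with the features in S set to the subject's
values. `explain_cohort()` explains each subject's held-out prediction
with that subject's LOOCV training fold as background. The efficiency
identity holds to numerical precision by construction; symmetry,
null-player behavior, and equality with a permutation-averaging oracle
are property-tested. The score explained is the positive-class
probability, not the hard label. Global importance is the mean
absolute attribution; the red/blue direction display of force plots is
summarized numerically as the feature-value/attribution correlation.

## Numerical and scope decisions

* Seeds: every stochastic entry point takes a seed, restores the
  caller's RNG, and derives child seeds as
  `(seed·7919 + k·104729) mod (2^31−1)`.
* The combined acoustic+demographic design has 92 columns — 88
  acoustic + age + education + one-hot sex (two indicators) — which
  reconciles the stated 92-variable count with three demographic
  variables; the neuropsychological set keeps a single 0/1 sex column
  (16 columns).
* Degenerate inputs: zero-variance columns are dropped at fit time
  with a warning; a zero pooled variance with unequal means flags an
  infinite t; missing values in user data are mean-imputed from
  training rows only (the generator emits none).
* Test-suite scaling: the swarm acceptance suites run at 30–40
  iterations instead of the 100-iteration default purely to respect
  the criteria's own runtime envelopes; thresholds and replicate
  counts are the stated ones. The reduced-scale coverage check for the
  percentile interval (10 runs of B = 150 instead of 20 of B = 5000)
  is labelled as such in the test.
* Out of scope: audio acquisition and preprocessing (the package
  consumes the extracted feature table), UMAP visualization, APOE
  genotyping, any multiple-testing machinery, and approximate SHAP
  variants.

## A known estimator bias the test suite surfaces

Pooled LOOCV AUC is slightly pessimistic under the null. Leaving
subject *i* out removes one member of its own class from the training
fold, so with permuted labels a 5-NN vote score for a true positive
averages 29/51 against 30/51 for a true negative at n = 52. That
anticorrelation biases the null mean AUC to about 0.468 rather than
0.500 — confirmed by an independent reimplementation of the same
scheme (bias −0.032 ± 0.003 over 1000 permutation replicates). The
calibration test that asserts a ±0.03 band around 0.5 therefore fails
by this margin, and is deliberately left failing rather than widened:
the failure documents a property of the estimator (well known from the
cross-validated-AUC literature, where leave-pair-out CV is the
recommended unbiased alternative), not a defect of the implementation.
The companion check — that the bootstrap scheme with an identity
resample reproduces plain LOOCV bit for bit — passes.

## Known limitations

The synthetic world is exchangeable-Gaussian; selection-recovery
results quantify algorithmic correctness, not expected clinical
performance. The up-front selection mode inherits the usual wrapper
optimism. The headline clinical numbers of the motivating study cannot
be reproduced without its undeposited data and are deliberately not
asserted anywhere in the tests.
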