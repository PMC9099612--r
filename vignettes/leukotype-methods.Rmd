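---
title: "Methods: calibrated centroid subtyping of B-ALL from RNA-seq counts"
author: "leukotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated centroid subtyping of B-ALL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `leukotype`, the
assumptions it makes, the parameters that matter, what the synthetic data
generator does and does not emulate, and the numerical and design choices
taken where more than one reasonable option existed. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## 1. Problem setting and assumptions

B-cell acute lymphoblastic leukemia is stratified into molecular subtypes
defined by genomic lesions. The transcriptome carries a strong imprint of
these lesions, so expression can stand in for direct lesion detection —
provided two pitfalls are handled:

* **Cohort confounding.** Multi-cohort training data mix batches (data
  source × age stratum) whose subtype composition differs. Naive batch
  correction then removes biology; no correction leaves technical structure
  for the classifier to learn. `leukotype` assumes batch effects are
  additive per gene on the log2 scale and estimates them only from
  *genetically matched subsets* — samples that share a lesion profile
  across batches — so that composition differences cannot masquerade as
  batch effects.
* **Single-sample deployment.** In a diagnostic lab, a sample arrives
  alone: no size-factor cohort, no batch label, no opportunity to
  re-normalize. All training-time parameters (standardization center and
  scale, centroids, calibration coefficients) are frozen in the model and
  applied to one sample at a time; the classification of a sample never
  depends on what else is in the same call. Classification must therefore
  be robust to residual per-gene offsets the incoming sample still carries,
  which is why the biomarker similarity is a Pearson correlation (invariant
  to sample-level shift and scale) rather than a Euclidean distance.

A further design commitment: training labels must come from observable
genomic lesions, never from expression clustering, so that the classifier
cannot be rewarded for rediscovering its own inputs.

## 2. The pipeline

### 2.1 Filtering and normalization

A gene is *usable* if it reaches `usable_min_count` (default 100) reads in
at least `ceiling(usable_min_fraction · n)` samples (default 1%, with a
floor of one sample — conservative for small cohorts) in **both** the
training and validation datasets. Normalization is the standard
median-of-ratios method: the reference is the per-gene geometric mean over
samples, restricted to genes with no zero count; each sample's size factor
is the median ratio to that reference. Expression is `log2(count/sf + 1)`.

### 2.2 Confounder adjustment

Within each batch, subtype-group means are subtracted (protecting labelled
biology by construction), the top `n_surrogates` (default 5) principal
directions of the residual matrix are removed by projection, and group
means are restored. The count is fixed rather than estimated: the operation
is deterministic, seed-free, and cannot remove variance that lies in the
protected group means. Nuisance variation that coincides exactly with a
subtype indicator is intentionally preserved — it is indistinguishable from
biology within one batch.

Between batches, each gene receives one additive offset per batch,
estimated from matched groups: each group contributes its per-batch
deviation from the group grand mean, weighted by group size. The estimate
is iterated to convergence (backfitting), which makes the operation
idempotent and preserves the grand mean exactly — a one-shot weighted mean
is not idempotent once several matched groups with unequal batch
composition are involved. Genes that are constant within every batch but
differ between batches, or expressed in only one batch, carry no usable
signal and are excluded (`perfectly_aligned`).

The *stability filter* then compares each gene's adjusted and unadjusted
expression; genes with Pearson `R < stability_r` (default 0.9) are
considered confounder-dominated and excluded. Zero-variance genes, whose
correlation is undefined, are excluded as a fail-safe.

### 2.3 Panel selection

For each gene and subtype, a one-vs-rest Welch t statistic (Welch–
Satterthwaite degrees of freedom; samples labelled `Undefined` excluded
from both groups) is mapped through the cumulative t-distribution and the
normal quantile to a Z-score. Tail probabilities are clipped to
`[1e-15, 1 − 1e-15]` so that quantiles stay finite; the clip constant is a
package decision. The per-gene score is the population variance of its
Z-row; genes are traversed in descending score order (ties broken
lexicographically by gene ID, another fixed package decision) and accepted
only if `|R| < prune_r` (default 0.3, with the boundary counting as
correlated) against every already-accepted gene, until `panel_size`
(default 45) genes are selected. Selection sees training data only.

The pruning rule deliberately caps how many mutually correlated genes one
transcriptional program can contribute, which spreads the panel across
subtypes; the selection trace (which gene blocked which) is kept in the
`gene_panel` object for audit.

### 2.4 Centroids, proximity, exclusivity

Standardization is robust: per-gene median center, MAD scale (×1.4826,
falling back to the standard deviation and then to 1 when zero) and
winsorization at ±`winsor_limit` (default 3) standardized units. The
protections-for-outliers mechanism is pinned down explicitly here because
only its intent, not its exact form, is otherwise fixed.

Each category's centroid is the mean standardized expression of its
training samples over the panel (subtype panel minimum 2 cases; driver
panel minimum `min_combo_cases = 5`). The biomarker similarity of a sample
is its Pearson correlation to each centroid; the predicted category is the
nearest centroid (exact ties resolve to the lexicographically smallest
name, and a tied top similarity forces exclusivity to 0).

Calibration is a one-vs-rest probit regression of category membership on
the similarity plus sex and age, fitted by weighted maximum likelihood with
class weights inversely proportional to class size (so the fit is invariant
to duplicating a class) and a small ridge penalty (1e-4, intercept
unpenalized) that keeps coefficients finite under perfect separation.
Covariate encodings are frozen at training time: sex M=0/F=1 with missing
set to the training mean; age standardized by training mean/sd with missing
set to 0. Categories with fewer than two positives cannot be calibrated and
fall back, flagged, to a rank transform of the similarity against the
training similarities.

The *proximity* of a sample to category k is `Φ(β₀ + β₁ s_k + β₂ sex +
β₃ age)`; the displayed *frequency estimate* is the proximity of the
predicted category. *Exclusivity* converts the gap between the best and
second-best proximity into a probability: both are mapped to the probit
scale (clipped to `[1e-12, 1 − 1e-12]`), and `(z_b − z_s)²/2` is referred to
the χ²(1) distribution. The variance-2 normalization makes the statistic
scale-correct for a difference of two standard-normal quantities and sends
a zero gap to exclusivity 0; this exact form is a package interpretation of
the (under-specified) published description, as is the use of the probit
rather than the raw probability scale. A single category yields exclusivity
1 by convention.

Quality gates (both default 50%): a sample is `Unclassified` when no
category reaches the proximity threshold, or when more than half of the
panel genes are absent from its input; otherwise `Ambiguous` when
exclusivity falls below its threshold; otherwise `OK`.

### 2.5 Driver and tissue panels

The driver panel applies the same machinery to pseudo-subtype labels — the
canonical comma-joined sorted set of lesion-harboring gene symbols (so
`BCR::ABL1` becomes `ABL1,BCR`). Canonical sorting is chosen for
determinism even though printed fusion order may differ; labels are
mutually exclusive per sample by construction, and only combinations with
at least `min_combo_cases` training cases are kept.

The tissue panel uses the same centroid-and-probit machinery on reference
expression profiles (one group per tissue, whole blood included), with one
deliberate difference: its standardization parameters are fitted on the
**reference collection**, not on the leukemia cohort. Against its own
cohort's median every patient is featureless (z ≈ 0), so a correlation
matcher anchored there cannot recognize "typical B-ALL"; against the tissue
collection the B-ALL profile is a strong, recognizable pattern. The
leukemia reference group is expected to consist of patient-like profiles.

### 2.6 Evaluation

Train/test splits are randomized separately within each subtype (and
within `Undefined`) so subtype frequencies match; a single-sample stratum
goes to training with a warning. Metrics are PPV-centred with NPV,
sensitivity, specificity and rank-based (midrank) AUC; intervals are Wilson
score intervals (the interval method is a package choice — it behaves well
at the small case counts typical of rare subtypes). Ratios with zero
denominators are reported as unavailable, never as 0. The three-tier report
computes each metric on all samples (an undefined-subtype sample predicted
into a category counts as a false positive — conservative), on
defined-subtype samples, and on defined samples whose call passed both
quality gates.

## 3. The synthetic data generator

`simulate_cohort()` draws negative-binomial counts with log2-scale additive
structure: per-gene baseline `N(5, 2)`; subtype marker effects; per-batch
per-gene offsets (sd 0.5); per-library-format per-gene offsets (sd 0.25);
per-sample log2 library size (sd 0.3). The default design has two batches
(pediatric, adult; 300 samples each), six distinct subtypes with 30 marker
genes each, and per-batch subtype frequencies that flip strongly between
batches (e.g. 0.22 vs 0.04) while keeping overall prevalences similar —
batch is confounded with biology by design, which is precisely the
structure the adjustment stage must untangle. The per-batch frequency
remainder (30%) is `Undefined`. Sex is Bernoulli(0.5); age is
batch-conditional normal (7 ± 4 pediatric, 45 ± 15 adult). A fraction of
defined-subtype samples (default 5%) have *low leukemia burden*: their
expected counts are the mixture `λ·ALL + (1−λ)·whole-blood` (default
λ = 0.3) at the count-mean level.

Two choices deserve justification:

* **Effect-size heterogeneity.** Marker effects are `effect ·
  Gamma(shape 2, rate 2)` per gene (mean = the configured effect, default
  2 log2 units). Real subtype signatures are long-tailed — a few strong hub
  genes (DUX4 being the extreme case) and many moderate responders. A
  generator with one uniform effect size per subtype produces a single
  shared expression direction per subtype, which makes all of a subtype's
  markers nearly collinear; the decorrelation pruning then collapses each
  signature to one or two genes, a degeneracy no real cohort shows.
* **Dispersion.** The negative-binomial dispersion (default 0.3) reflects
  combined technical and patient-to-patient biological variability of bulk
  tumor RNA-seq, at the upper-middle of cohort-level estimates — patient
  cohorts are far noisier than cell-line replicates.

What the generator does **not** emulate: correlated co-expression modules
beyond the subtype programs themselves; gene-length and GC effects;
count-depth heteroscedasticity beyond the NB mean-variance law; partially
overlapping signatures between subtypes (e.g. a central supergroup whose
members shade into one another); label noise in the lesion annotations; and
the long tail of rare subtypes. Passing tests therefore demonstrate that
the pipeline recovers the structure it assumes, under realistic noise and
deliberate confounding — not that real-data performance will match.

`simulate_tissue_reference()` shares gene-level parameters with the cohort
generator (same config and seed ⇒ same synthetic world), so the whole-blood
profile used for low-burden blending is the same profile the tissue panel
trains on.

## 4. Numerical choices and degenerate inputs

* Welch-Z tail clip `1e-15`; probit-scale clip `1e-12` in exclusivity.
* Zero-variance genes: scale falls back MAD → sd → 1; zero-variance
  candidates are skipped by the pruning (they cannot serve as biomarkers);
  zero-variance sample vectors get similarity 0 everywhere, proximity 0 and
  an `Unclassified` flag.
* Ties: gene ranking ties break lexicographically; nearest-centroid ties
  resolve to the lexicographically smallest category and force
  exclusivity 0.
* Batch alignment backfitting stops at a 1e-10 maximum offset change or
  100 iterations.
* The model archive is versioned JSON; doubles are written as
  17-significant-digit decimals, which round-trip IEEE values exactly while
  keeping the file diffable. A schema-version mismatch is a hard error.
* Single-sample classification uses a unit size factor: a lone sample has
  no cohort to share a median-of-ratios reference with, and the
  correlation-based similarity absorbs the resulting global shift.

## 5. Problem sizes used by the test suite

The suite and the acceptance script run entirely on simulated data at
deliberately modest sizes, chosen as the smallest scales at which the
statistical properties under test are stable: 2 000 genes throughout;
600-sample cohorts for the confounding and quality-gating checks;
900 samples (600 train / 300 held out) for strong-signal recovery; 1 800
samples for the null-recovery check, where per-category PPV estimates need
a wide test set to sit well inside the ±0.1 comparison band; 100 random
instances for the pruning oracle and 1 000 for the nearest-centroid oracle.
The full suite runs in well under a minute on one CPU.

## 6. Known limitations

* The matched-subset batch alignment estimates *additive* per-gene offsets;
  multiplicative or rank-distorting batch effects are only partially
  removed and will instead be caught (and discarded) by the stability
  filter.
* Balanced probit calibration deliberately prices rare categories up; with
  very weak signals this makes the proximity gate permissive (a featureless
  sample can brush a centroid by chance), which is why abstention is
  distributional, not absolute — a small share of pure-noise profiles will
  pass the proximity gate.
* The tier-3-over-tier-2 PPV improvement is a strong tendency, not a
  theorem: at near-ceiling PPV, removing flagged samples can lower a
  category's PPV by one sample's worth when the single residual error
  passed QC.
* Rare categories (driver combinations below `min_combo_cases`, subtypes
  with a single case) are dropped rather than modelled; the package reports
  what it cannot calibrate instead of guessing.
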