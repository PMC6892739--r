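---
title: "Methods: integrated gene prioritization from variant and phenotype evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated gene prioritization from variant and phenotype evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pediar)
```

## The model

For each case, every candidate gene `g` in the exome is described by a
five-dimensional evidence vector
`x_g = (cadd, gestalt, feature_match, phenomizer, boqa)`:
the maximum variant deleteriousness in the gene (CADD-PHRED scale), a
photo-derived per-syndrome gestalt similarity mapped to gene level, and
three semantic similarities between the patient's HPO terms and the
annotation of the gene's syndromes. A soft-margin linear SVM is trained on
the pooled standardized rows of all training cases, with the causal gene of
each case labelled true, and the *PEDIA score* of a gene is the signed,
unnormalized margin

$$s(g) = w \cdot \tilde{x}_g + b, \qquad \tilde{x}_g = (x_g - \mu)\,/\,\sigma,$$

where `μ`, `σ` are per-feature location and scale fitted on the training
rows only. We use the margin rather than the geometric distance
`(w·x+b)/‖w‖`: ranking is identical and the constant is avoided. Genes are
ranked by descending score; ties take competition ranks and are ordered
lexicographically by symbol so every run is reproducible.

Assumptions worth keeping in mind:

* evidence is additive on the standardized scale — a linear kernel; no
  interactions between evidence channels are modelled;
* exactly one causal gene per case (the label layout enforces it);
* phenotype similarity is informative at syndrome level and transfers to
  genes through the syndrome–gene map by taking the per-gene maximum over
  linked syndromes, so locus heterogeneity never penalises a gene.

## Semantic similarity scores

The package computes its three HPO-based scores from an OBO 1.2 ontology
and a disease→term annotation catalog:

* **Information content.** `ic(t) = −ln(n_t / N)` where `n_t` counts
  diseases whose ancestor-propagated annotation closure contains `t` and
  `N` is the catalog size; `ic(root) = 0`. A term no disease reaches gets
  `max(ic) + ln 2` — treated as maximally informative — which keeps `ic`
  monotone along every `is_a` edge. Natural-log units throughout; the
  downstream classifier learns its own scale, so units cancel.
* **Phenomizer-style score.** Symmetric Resnik best-match-average: each
  query term's best match against the disease annotation and vice versa,
  the two directional means averaged. The symmetric mode is a declared
  default, not an inference about any external tool; the asymmetric
  query-to-disease mean is a one-line change. No sampling-based p-value
  step: raw similarities feed the classifier.
* **Bayesian ontology query.** Exact enumeration of the two-noise-rate
  observation model over the term universe: false-positive rate
  `α = 0.001`, false-negative rate `β = 0.1`, uniform disease prior.
  Computed in log space and normalised over diseases; at the catalog sizes
  used here the exact form is fast and sidesteps any sampling
  approximation. `α`, `β` and the prior are exposed.
* **Feature match.** The corresponding commercial score is unpublished, so
  the package ships a transparent stand-in — the Jaccard overlap of the
  ancestor closures of query and annotation — and exposes the scorer as a
  pluggable function slot so externally computed clinical-feature scores
  can be injected unchanged. The pipeline only requires a monotone
  clinical-feature similarity in this column.

Multiple inheritance is fully supported: closures are unions over all
`is_a` paths.

## Exome side

Variants arrive as a VCF 4.x with configurable INFO keys (defaults
`CADD_PHRED`, `GENE`, `AF`, `CSQ_CLASS`). Multi-allelic records are split
per ALT before filtering; a missing allele frequency is treated as 0
(assume rare — the spike-in benchmark favours sensitivity). Filtering is a
parameterized simplification of trio-style rare-disease triage: frequency
cutoff (default 0.01), allowed consequence classes, optional score floor.
Genotype and inheritance-mode reasoning are deliberately absent, because
the per-gene reduction that follows takes the *maximum* deleteriousness per
gene regardless of genotype — a sensitivity-maximising heuristic for
compound-heterozygous recessive cases whose second hit scores low.
Benchmark cases are created by spiking the causal variant's score into a
background per-gene map: the causal entry becomes
`max(background, causal)`, nothing else changes.

## Classifier choices

* **Standardization.** Per-feature location/scale fitted on training folds
  only, using the population (1/n) standard deviation. Raw CADD (~0–40)
  would otherwise dominate posterior-scale features (~0–1). The 1/n
  convention makes the scaler invariant under row duplication, which the
  test suite exploits as an exact refit identity (duplicating all rows
  while halving the per-row cost reproduces the decision function).
* **Class imbalance.** One causal row among hundreds per case. The hinge
  loss is weighted by inverse class frequency (`n/(2·n_class)`); no
  subsampling, so training is deterministic and uses every row.
* **Hyperparameter.** The cost `C` is selected from a grid of integer
  powers of two spanning `2^-6`–`2^12` by internal k-fold cross-validation
  over *cases* (default five folds), maximising top-1 accuracy; ties break
  to the smallest `C`. Granularity within the range is a package choice.
* **Orientation.** The underlying LIBSVM fit may return the hyperplane
  with either sign depending on label encounter order; after fitting, the
  weights are flipped if needed so causal-labelled training rows score
  higher on average. Termination tolerance is tightened to `1e-6` so
  refit identities hold to the tolerance the tests assert.
* **Missing phenotype scores.** Genes whose syndromes carry no score take
  the fill value 0 — scores are nonnegative similarities and 0 is their
  natural floor. The mapping stage deliberately leaves such genes absent
  rather than zero-filled so that "unscored" remains distinguishable until
  the fill is applied.
* **Degenerate inputs.** Single-class training data, non-finite features,
  empty rank maps and out-of-range noise rates raise immediately with the
  offending gene/field named; all-zero weight vectors make the
  contribution split undefined and error rather than return NaN.

## Evaluation design

Folds are gene-disjoint: cases are grouped by causal gene and gene-groups
are packed into k folds greedily, largest first, balancing *case* counts
(the disjointness constraint is the requirement; the balancing objective is
a package choice), with seeded shuffling of equal-sized groups. Ablations
shrink the feature vector to the active columns instead of zero-filling,
so a single-score combination reduces exactly to sorting by that score —
the CADD-only baseline is a pure sort. Accuracy is reported per case.

The transfer experiment evaluates phenotype-only cases (gestalt vector and
diagnosis, no usable exome): each such case borrows the molecular and
clinical-feature columns of a uniformly sampled same-diagnosis donor from
the training cohort, the donor's gene table and causal label are inherited,
and only the gestalt column is replaced by the test case's own gene-mapped
scores. Since the molecular columns are wholly the donor's, inheriting the
donor's label is the only internally consistent choice when a diagnosis
has several genes. Training cases sharing a test case's causal variant
(same gene and score) are excluded before training. Repeats resample
donors only; the model is fitted once. With a single donor per diagnosis
every repeat is identical and the SD is exactly 0 (also the convention for
one repeat).

## What the synthetic generator emulates — and what it does not

`synthetic_config()` builds a rooted DAG (window-limited parent choice for
depth, optional second parents), a disease catalog, a syndrome–gene map
with configurable locus heterogeneity (default 2 genes/disease), noisy HPO
queries (25% term dropout, 10% noise-term rate), gestalt vectors with a
truncated-normal baseline (mean 0.2, sd 0.1) plus a mean shift
(default 0.5) on the true syndrome, and per-ethnicity background exomes.
Background per-gene deleteriousness is `Beta(2,5)` scaled to `[0,40]`
(right-skewed, most genes low-scoring); causal scores are `Normal(28,4)`
truncated at 0. These are plausible CADD-PHRED shapes chosen once as
simulation parameters, not estimates of any real cohort. Ethnicity affects
only the background gene count (African-ancestry backgrounds larger at a
comparable score distribution), mirroring the observation that variant
load differs across populations far more than rare-variant score
distributions do.

Every stage draws from its own derived seed substream, so extending a
cohort reproduces its earlier cases byte-for-byte.

What passing tests on these cohorts do **not** show: real gestalt score
distributions (the generator's truncated normals are far better behaved
than classifier outputs on uncontrolled photographs), real allele spectra
or gene length effects, correlated noise between the three HPO scores
(they share a query here, but real tools also share curation biases),
phenotypic-series structure, or cases whose photo is missing entirely.
Accuracy numbers on synthetic cohorts characterise the pipeline's
mechanics, not expected clinical performance.

## Problem sizes

The test suite exercises oracle equivalence on ≥200 random DAGs of ≤50
terms, reduction oracles on 1,000 random instances, fold audits on 100
random cohorts, a 1,000-case null calibration against the 10/N binomial
band, and a 20-seed paired comparison of the five-score model against the
CADD-only baseline on 200-case, 20-disease cohorts with 2-fold
gene-disjoint CV and a single-point C grid — sizes chosen to keep the full
suite in the minutes range on one core while leaving each property
statistically meaningful. The acceptance script runs the generator
defaults (100 cases, 20 diseases) with tenfold CV and a seven-point C grid.

## Known limitations

* The feature-match column is a stand-in; conclusions about its relative
  weight do not transfer to the commercial score.
* OMIM phenotypic series are not expanded; only explicit syndrome→gene
  rows map.
* No nonlinear kernels, probability calibration, or inheritance-aware
  variant logic.
* The spike-in design assumes the causal variant would survive filtering;
  real-world filter misses are invisible to this benchmark.
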