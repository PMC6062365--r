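---
title: "Integrating chemical, protein-target and cytotoxicity descriptors for acute-toxicity classification"
author: "toxtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating chemical, protein-target and cytotoxicity descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxtriad)
```

## The modelling problem

Acute oral toxicity in the rat is recorded as pLD50, the negative decadic
logarithm of the median lethal dose in mol kg⁻¹; larger values mean more
toxic.  Compounds with pLD50 < 2 are classed nontoxic, those with
pLD50 > 3 toxic, and the band in between is *marginal* and excluded from
modelling (the inequalities are strict, so a value of exactly 2 or 3 is
marginal).  The benchmark cohort this package emulates contains 367
compounds, 275 nontoxic and 92 toxic.

The classification question is whether *heterogeneous* descriptor domains
— information sources of fundamentally different provenance — improve the
prediction of this organism-level endpoint over conventional
structure-only QSAR:

* **chemical**: 192 numeric 2D structure/physicochemistry descriptors;
* **target**: 477 in-silico protein-target interaction-likelihood scores
  from a Laplacian-modified naive Bayes multi-target model trained on
  bioactivity data;
* **cytotox**: 182 qHTS cell-viability dose-response descriptors
  (13 cell lines × 14 concentrations between 0.6 and 92 µM, each curve
  scaled to unit maximum response).

Seven random-forest classifiers — one per non-empty subset of the three
domains — are compared under a shared, repeated, class-stratified
cross-validation design.

## The target scorer

The multi-target scorer `lmnb()` stores, for every retained target $t$,
Laplace-corrected feature counts over its active training compounds.  A
compound with binary feature set $x$ (a circular-fingerprint bit set)
receives the score

$$\mathrm{score}(t, x) \;=\; \sum_{f \in x}
  \ln \frac{A_{t,f} + 1}{N_f\, P_t + 1},$$

where $A_{t,f}$ counts active compounds for $t$ containing feature $f$,
$N_f$ counts training compounds containing $f$, and
$P_t = n_{\mathrm{active},t} / n_{\mathrm{records},t}$ is the target's
base rate.  A feature never seen in training contributes
$\ln(1/1) = 0$.  The scores are relative interaction likelihoods — the
quantity a Bayesian classifier would threshold for class membership —
not predicted affinities, and they are used directly as numeric
descriptors.  Targets with fewer than 50 bioactivity records, or with a
degenerate base rate, are dropped and reported.

Two properties worth knowing: scores are additive over disjoint feature
sets, and the per-feature ratio $A_{t,f}/N_f$ being above or below the
Laplacian-neutral value determines the sign of a feature's contribution.
A consequence we rely on in the synthetic-data design: the formula
compares a per-target active count against a pool-wide expectation
$N_f P_t$, so if each target's records cover only a subsample of the
training pool, every seen feature acquires a spurious negative weight
and scores degenerate into (negative) fingerprint sizes.  The synthetic
bioactivity table therefore assays every target against the whole pool.

## Preprocessing, fitted inside every fold

Four steps run strictly in this order, per descriptor domain, fitted on
the modelling (4/5) set only and applied unchanged to the held-out fold:

1. **Near-zero-variance filter** — drops constant columns and columns
   whose most-common/second-most-common frequency ratio exceeds 19 while
   fewer than 10% of values are distinct (conventional defaults; the
   benchmark prints none).
2. **Per-domain correlation cutoff** — greedy elimination: while any
   column pair exceeds the domain's cutoff in absolute Pearson
   correlation, the member of the worst pair with the larger mean
   absolute correlation *to all columns of the input table* is removed
   (exact ties break on column name).  Ranking against the full input
   table, rather than the shrinking survivor set, makes a single
   descending sweep over the sorted pair list exact and deterministic.
   The cutoffs themselves are calibrated once on the full dataset by
   bisection so every domain shrinks to within ±10% of a common width
   (the smallest post-filter domain width by default) — this prevents
   one domain from dominating the forest's feature sampling.  A strict
   fold-internal recalibration mode is available via
   `preprocess_config(recalibrate_per_fold = TRUE)`.
3. **Range scaling** to $[0,1]$ using modelling-set minima and maxima.
   External values may fall outside $[0,1]$ and are deliberately not
   clipped; a column constant in the modelling set maps to 0.
4. **Downsampling** — each nontoxic modelling compound's Euclidean
   distance to its nearest toxic modelling compound is computed in the
   post-scaling *chemical* block, and only the
   $\lceil \mathrm{ratio} \times n_{\mathrm{toxic}} \rceil$ nearest are
   kept (ratio 1 by default, giving an approximately class-balanced
   training set).  The chemical block is used for the distances even
   when the modelled combination excludes it, because class balancing
   in chemical space is a property of the study design, not of the
   descriptor subset being evaluated; only a dataset with no chemical
   block at all falls back to the modelled descriptors.

No information from a held-out fold can reach any fitted parameter; the
test suite asserts this by perturbing external rows and requiring an
identical `preprocess_state` and an identical trained forest.

## Cross-validation design and the learner

`make_split_plan()` builds 20 repeats (5 in the scaled-down test
profile) of 5 class-stratified folds by dealing shuffled within-class
indices round-robin, so every fold's class counts are within one
compound of perfect stratification.  The *same* plan is reused for every
domain combination, which is what makes paired comparisons meaningful.

The learner is a 500-tree random forest with
`mtry = floor(sqrt(p))`, where $p$ is the post-preprocessing descriptor
count of that particular fold (so `mtry` is recomputed per fold).
Predicted class is the majority vote; `p_toxic` is the fraction of trees
voting toxic; exact ties classify as toxic, because a false negative is
the costlier error in toxicology.  Performance is summarized as
sensitivity (fraction of toxic compounds recovered), selectivity
(fraction of nontoxic compounds recovered) and CCR, their arithmetic
mean.

Master-seed handling: every (repeat, fold, combination, scramble) cell
derives its own child seed from the master seed through a fixed integer
recurrence, so whole studies are reproducible bit for bit and individual
cells can be recomputed in isolation.

## y-randomization

For an assessed cell, the modelling-set labels are permuted uniformly
`n_scrambles` = 10 times and the *entire* pipeline — including
downsampling — is retrained each time; the external fold keeps its true
labels.  The real model's external CCR is compared with the scrambled
distribution through the prediction-interval form

$$t = \frac{\mathrm{CCR}_{\mathrm{real}} - \overline{\mathrm{CCR}}_{\mathrm{scr}}}
          {s_{\mathrm{scr}}\sqrt{1 + 1/n}},\qquad df = n - 1,$$

one-tailed.  Under exchangeability of the real and scrambled models this
statistic is calibrated (type-I rate 0.05); the naive one-sample form
with standard error $s/\sqrt{n}$ would compare one observation against
the *mean* of the scrambled distribution and reject far too often.  If
the scrambled CCRs are all identical, the degenerate rule applies:
p = 0 if the real CCR exceeds the common value, else 1.  A model passes
at p < 0.05.

**A caveat discovered while validating this machinery.**  When the
pipeline's downsampling step is retrained inside each scrambled run,
scrambled models can be *genuinely* predictive of the true labels: all
scrambled-"toxic" compounds are kept, while scrambled-"nontoxic"
compounds survive only if chemically close to them, so sparsely
populated regions of chemical space end up almost purely
toxic-labelled in the scrambled training set.  If the truly toxic class
itself occupies low-density chemical space — as it does whenever
descriptors encode the toxicity signal strongly and toxic compounds are
a distributional tail — the scrambled models inherit real signal
through density alone.  The package's power check therefore uses a
signal-bearing cohort whose toxicity signal is carried by the target
and cytotoxicity domains (chemical weight 0), keeping chemical-space
density toxicity-neutral.  Practitioners running y-randomization with
density-biased class balancing inside the pipeline should be aware of
this coupling.

## Evaluation suite

* `summary()` of a `toxcv` fit gives per-combination mean ± SD of
  sensitivity, selectivity and CCR over all cells.
* `paired_improvement()` computes per-cell CCR differences over the
  shared splits, with mean, SE = SD/√n and a two-tailed paired t-test
  (identical inputs give p = 1 by the zero-variance rule).
* `roc_auc()` is the rank-based (Mann–Whitney) AUC with ties counted
  half; it is invariant under strictly monotone score transformations.
* `mantel_test()` correlates the upper triangles of two distance
  matrices with significance from joint row/column permutations,
  p = (1 + #{r* ≥ r}) / (1 + n_perm).
* `ad_profile()` bins every external prediction by Euclidean distance
  to its fold's modelling set, measured in a chemical space
  preprocessed once on the whole dataset (whole-dataset cutoffs, as in
  descriptor-space figures), with pooled quantile bin edges shared
  across combinations.  The default distance reference is the full 4/5
  modelling membership; a `"trained"` variant measures distance to the
  post-downsampling training compounds instead, which is better read as
  distance to the class-boundary region than as chemical novelty.
* `aggregate_importance()` range-scales each fold model's Gini
  importances to [0, 100] and averages each descriptor over the models
  in which it survived preprocessing (no zero-imputation; the count of
  contributing models is reported).
* `neighbor_contrast()` finds a toxic query's k = 5 nearest nontoxic
  neighbours in chemical space and lists, per neighbour, the m target
  descriptors with the largest score increase from neighbour to query;
  targets recurring in at least 3 of the k lists are flagged as
  implicated in the query's mode of action.

## The synthetic cohort generator

`generate_cohort()` draws a full study dataset with known ground truth,
so that every stage of the pipeline — and every directional claim about
it — is testable without external data.  Its defaults are the study
conditions: 367 compounds with a 275:92 nontoxic:toxic split, 192
chemical descriptors, 477 targets, 13 cell lines × 14 concentrations
between 0.6 and 92 µM.

The generative skeleton is a set of 12 latent toxicity mechanisms
(half-normal activations, assigned round-robin to the three domains)
plus 12 toxicity-irrelevant nuisance factors:

* **pLD50** is a weighted sum of standardized per-domain mean
  activations, mapped through a deliberately bimodal transform (a gap
  around the marginal band, so only noise places compounds in it) and
  Gaussian noise; the noise is resampled until the thresholded class
  counts land within 15% of the configured 275:92 split (at most 100
  attempts, then an explicit failure).  The default domain weights are
  0.45/0.275/0.275 (chemical/target/cytotox), matching the published
  regime in which the chemical-only model is the strongest single
  domain.
* **Scaffold clusters**: compounds belong to 12 clusters with Zipf-like
  sizes; each cluster carries an offset in chemical-descriptor space
  (SD 0.8) and a cluster-level toxicity effect that supplies 30% of the
  chemical signal share.  The cluster effect cannot be learned for
  scaffolds missing from a training split, and the offsets make
  rare-cluster compounds chemically novel — together this is the
  minimal structure that produces applicability-domain decay, the
  empirical signature that accuracy falls with distance from the
  training data.
* **Fingerprints**: each latent factor owns a small block of bits that
  switch on with probability increasing in its activation, over a 2%
  background rate.
* **Chemical descriptors** read out one chemical-facing mechanism each
  (sparse loadings, like real descriptors measuring specific
  properties), plus the cluster offset and noise.
* **qHTS curves** follow a Hill model
  $E_{\max} c^h / (EC_{50}^h + c^h)$; a compound-level base potency is
  shared across cell lines with per-line jitter, and cytotox-facing
  activation lowers $\log_2 EC_{50}$, so the scaled curves carry the
  cytotox signal share.  With `noise_sd = 0` the curves are exactly
  nondecreasing in concentration.
* **Bioactivity**: a third of the targets link to target-facing
  mechanisms (a primary mechanism blended with a random secondary one,
  so linked targets are not mutually redundant); the rest are decoys
  driven by nuisance factors with the same link form, giving the whole
  target block protein-family-like correlation structure.  Without
  this, the domain-size correlation filter would remove exactly the
  mechanism-linked targets, since they would be the only correlated
  columns.  Every target is assayed against the whole 600-compound
  pool (see the scorer section for why).

The latent ground truth (activations, facing assignment, cluster
membership, target links) is stored under `cohort$truth` for recovery
tests only; no modelling function reads it.

**What the generator does not emulate:** real chemistry (no valid
SMILES), assay-specific qHTS noise structure and its published
noise-filtering, inter-laboratory variability, and the long-tailed
potency distributions of real bioactivity databases.  Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* behaves as
designed — leakage-free preprocessing, calibrated robustness testing,
recovery of planted structure, directional benefit of integration —
not that any particular accuracy level transfers to real data.

## Problem sizes and numerical choices

The scaled-down test profile uses 5 cross-validation repeats (the full
design uses 20), five generator seeds for directional claims, 10
scrambles per y-randomization cell, 5 quantile bins for
applicability-domain profiles, and 999–4999 Mantel permutations; the
bundled acceptance script runs the full 7-combination study at 5
repeats on one cohort.  Bisection for cutoff calibration runs at most
40 iterations; correlation filtering treats undefined correlations
(constant columns) as zero; quantile bin edges use R's default type-7
quantiles; distance ties in downsampling and neighbour search break on
compound id, and score ties in neighbour contrasts on target id, so
every result is reproducible to the bit given the master seed.

## Known limitations

* Synthetic single-domain accuracies are not calibrated to the
  published values; only orderings and directions are designed to
  match.
* The greedy correlation filter does not minimize the number of removed
  columns (no greedy method does in general); it is deterministic and
  respects the cutoff bound, which is what the design requires.
* The y-randomization caveat above means scrambled-model performance is
  not a pure null reference whenever class density and class identity
  are coupled in the downsampling space.
* `aggregate_importance()` uses the forest's mean decrease in Gini
  impurity, which is known to favour many-valued descriptors; within a
  single homogeneous preprocessing regime this bias is shared across
  domains.
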