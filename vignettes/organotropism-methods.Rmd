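---
title: "Methods: predicting organotropic metastasis from primary-tumor transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting organotropic metastasis from primary-tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organotropism)
```

## The modeling problem

A primary tumor's transcriptome carries information about where — if
anywhere — it will metastasize. The package decomposes the question into a
multiclass stage (which tumor type is this?) and a family of binary
problems, one per (cancer type, metastatic site) pair: did tumors of this
type develop a recorded metastasis at this site (positive class) or not
(negative class, including tumors that metastasized elsewhere)? The
decomposition sacrifices features of non-mutually-exclusive multi-organ
progression — a tumor seeding both liver and lung contributes a positive
label to each site independently — in exchange for many well-posed binary
problems at realistic cohort sizes.

Three properties of real cohorts drive the design. First, positives are
rare: a site with eight to forty recorded progressions against hundreds of
negatives is typical, which motivates synthetic minority oversampling.
Second, the feature space (~60,483 transcripts) dwarfs the instances,
which motivates aggressive, variance-reduced feature selection. Third,
clinical annotation is free text, inconsistent in case, whitespace and
delimiters, and contains "synchronous" progressions whose diagnostic
ordering is ambiguous; these are excluded from labeling entirely rather
than guessed at.

## Label construction

`harmonize_sites()` recognizes the three site-column spellings found in
TCGA-style clinical files, splits multi-site cells on the delimiter set
{";", ",", "|"} (declared and configurable; free-text conventions vary),
trims and title-cases site strings, and flags synchronous rows.
Harmonization is idempotent, so pipelines may apply it defensively.

Pair filtering keeps a (cancer, site) pair when it has at least 8 positive
annotations and a total population strictly over 50. Both thresholds are
read literally: "at least eight" is ≥ 8 and "over fifty" is > 50, so a
(20-positive, 50-patient) pair is dropped while (8, 51) is kept. COAD and
READ are pooled as COADREAD before counting, reflecting their overlapping
metastatic behavior. A tumor that is negative for the tested site but
positive elsewhere counts as a negative instance — the negative class is
"did not progress to this site", not "did not progress at all"; the two
kinds of negatives are weighted identically.

## SMOTE with the 80% stopping rule

Synthetic minority samples are convex combinations `x_i + u (x_j − x_i)`,
`u ~ U(0, 1)`, of a minority instance and one of its k = 5 minority-class
nearest neighbors (Euclidean distance, distance ties broken by lower
instance index; k = 5 is the technique's classic default, adopted because
the balancing rule itself does not fix k). Oversampling stops when the
minority count reaches round(0.8 × majority), rounding half away from
zero so the "closest integer" is honored without banker's-rounding
surprises. Stopping at 80% rather than parity is an overfit guard: the
synthetic cloud should support, not dominate, the decision boundary.
Neighbors are searched within the minority class only. If the minority
class has fewer than k + 1 members, k is reduced to minority − 1 with a
warning; a 1-member minority is rejected. Every synthetic point records
its two parents and interpolation weight, which is what makes the leakage
audit (below) possible.

Balancing runs before feature selection, matching the architecture's
stage order (synthetic generation, then selection, then classification).
Selecting after augmentation can optimistically bias support scores — the
synthetic points echo the minority's structure — which is why evaluation
never touches synthetic data: the holdout is drawn from real samples
before SMOTE is fitted, so no test sample is ever a SMOTE parent, and
reported metrics are computed on real instances only.

## Blockwise consensus feature selection

The feature space is partitioned into `n_blocks` contiguous, nearly equal
blocks (100 blocks of ~605/604 features at full scale); each block is
scored independently by five selectors:

- **χ² filter** on features min-max scaled to [0, 1] (the statistic
  requires nonnegative input; constant features scale to zero and are
  never supported);
- **RFE** under a linear logistic estimator (a lightly ridge-regularized
  fit for numerical stability; if it fails to converge the regularization
  is increased once, then the block errors), dropping the lowest-|β| 10%
  of remaining features per round;
- **random-forest classifier** and **random-forest regressor** impurity
  importances (the regressor treats the 0/1 label as numeric), 100 seeded
  trees each;
- **L1-penalized logistic regression**, ranked by |coefficient| at the
  sparsest point of the path with at least the requested number of active
  features.

Each method supports its top `per_block_keep` features; votes (0–5) are
summed, and features are ranked by vote, then by the mean of per-method
scores normalized to [0, 1] within the block, then by lower feature index
— every tie-break is deterministic. Colinear features (|Pearson r| ≥ 0.95
against an already-kept feature; the threshold is a design choice, no
canonical value exists) are pruned greedily in rank order *before* the
per-block truncation, so the retained counts are post-pruning; a block
exhausted by pruning keeps all survivors and logs the shortfall.

The per-block keep count defaults to the explicit 50-per-block reading
(50 × 100 = 5000 candidates); `keep_fraction` implements the alternative
"top 10% of each block" reading (~60 of 605), which is not identical —
the two conventions coexist in the field and the count-based one is the
default here because it pins the candidate-set size exactly. An optional
`cv_folds` setting refits every selector leaving one fold out at a time
and demands majority-fold support; the default is a single fit per block,
since no fold count is canonical and the holdout protocol already guards
evaluation.

## Classifiers

The tumor-type stage is a gradient-boosted tree ensemble (300 rounds,
depth 3, learning rate 0.1 — conventional defaults, all configurable, run
single-threaded and seeded for determinism) over the full feature space;
block selection is defined per binary comparison and is not applied to
the multiclass problem. The per-pair binary models are random forests by
default (300 trees, probability forests) with a GBT option; both report a
posterior and classify by rounding it, with the exact 0.5 tie going to
the positive class — an arbitrary but fixed convention. The multiclass
split is stratified 70/30, mirroring the binary protocol. Classes with
fewer than two training samples trigger a warning (such populations are
too small to model; they are not silently dropped). Per-class precision,
recall and F1 come straight from the confusion matrix; macro averages are
unweighted means over classes present in the test set, and a class absent
from the test set is excluded with a warning rather than imputed.

## Recapture and enrichment statistics

Recapture asks whether two independently selected feature lists overlap
more than chance allows. Because every binary comparison starts from the
same complete transcriptome, that transcriptome is the background for all
recapture tests, regardless of which pair the lists came from. The test
is the hypergeometric upper tail P(X ≥ a) — one-sided, because the
alternative of interest is *enrichment* of the overlap; a two-sided
variant is available by flag. The odds ratio (ad)/(bc) is serialized with
an `"Inf"` sentinel when a margin is empty, with an optional
Haldane–Anscombe 0.5 correction (off by default, since the sentinel is
informative). Bonferroni is the only multiplicity correction offered,
`p_adj = min(1, m p)` with m at least the number of tests.

GO overrepresentation uses the same hypergeometric machinery per term,
with the background switched to the annotated transcript universe (a
transcript with no GO term cannot score in either direction), Bonferroni
over all tested terms, and a 0.05 threshold on the adjusted p-value.

### The multiplicity-weighted overlap null

Transcripts map to wildly different numbers of GO terms, so two random
transcript lists can share many "significant" terms purely through
heavily annotated transcripts. The simulation null quantifies this: per
replicate, two transcript lists are drawn without replacement with weight
∝ 1/m_i (m_i = the transcript's term multiplicity), each list is put
through the full overrepresentation test, and the overlap of the two
significant-term lists is recorded; a replicate with no significant terms
contributes overlap 0. Inverse proportionality is the simplest monotone
weighting that prioritizes sparsely annotated transcripts, and it is
exposed as a configuration hook (`weighting = "uniform"` disables it).
All unordered pairs of the configured list sizes are simulated — the
full-scale protocol is sizes 100–500 in steps of 100, 15 combinations at
50,000 replicates each (750,000 total); the package default is a
desk-scale 500 replicates per combination, with the full count one
configuration change away. Observed overlaps are compared against the
null's 95th percentile.

### Semantic clustering

Shared enriched terms are clustered on a similarity matrix whose entries
are the Jaccard index of the terms' inclusive is-a ancestor sets in the
GO DAG — a deliberate, documented simplification of information-content
and graph-based semantic similarities, chosen because it needs nothing
but the DAG and behaves sensibly at its extremes (identical terms score
1; terms sharing only the root score near 0). Clustering is recursive
bipartition (average-linkage cut into two) that stops when a cluster's
mean off-diagonal similarity reaches a threshold (default 0.6). Exact
replication of published semantic-similarity/binary-cut implementations
is a non-goal.

## The synthetic-cohort generator

`generate_cohort()` draws negative-binomial counts (variance
μ + φμ², dispersion φ = 0.3 by default — mid-range for bulk RNA-seq)
with log-normal baseline means (log-mean log 50, log-sd 0.6). Tumor-type
and tropism signatures are disjoint transcript sets whose log-means shift
by `effect_size` standard units, where the per-transcript noise SD on the
log scale is √(φ + 1/μ); shift signs are random, since real signatures
mix up- and down-regulation. Positives are drawn independently per
(cancer, site), so multi-site patients arise naturally. The clinical
table reproduces the field's annoyances on purpose: free-text site cells
with random case/whitespace variants and mixed delimiters, and a
configurable fraction of metastatic rows labeled "synchronous".
Defaults (15% positives per site, 10% synchronous) reflect the sparse
annotation typical of real cohorts. Ground truth (signature IDs, positive
IDs, synchronous IDs) is emitted as a separate JSON artifact that the
analysis pipeline never reads.

What the generator does *not* emulate: batch effects, library-size and
GC biases, correlated co-expression modules, purity gradients, or any
single-cell structure. Passing tests on synthetic cohorts therefore
demonstrate that the architecture recovers the signal it assumes — a mean
shift in a sparse transcript set — not that it is robust to every
artifact of production RNA-seq.

## Numerical choices and degenerate inputs

- All randomness flows through explicit integer seeds (forest seeds per
  block are derived as master + block index); fixed seeds give
  bit-identical cohorts, splits, models and manifests.
- Rounding of count targets is half-away-from-zero throughout.
- Zero-variance features: χ² scores 0, correlation treated as 0 in
  colinearity pruning, standardized to all-zeros for RFE.
- Single-class targets error early in every selector and classifier.
- Empty pair catalogs, empty enrichment results and zero-overlap tables
  are all valid outputs, not errors.
- The pipeline manifest records the package version, master seed, a
  configuration fingerprint and the md5 of every output; caching is at
  run level (a rerun with an identical fingerprint and hash-verified
  outputs is reused), which keeps the cached-equals-recomputed invariant
  checkable with nothing but file hashes.

## Validation scale

The test suite validates at desk scale: cohorts of 100–300 samples and
240–2000 transcripts, selection over 2–10 blocks, forests of 50–300
trees, and 500-replicate overlap nulls. These sizes were chosen so the
full suite exercises every stage — including two complete
planted-signal recovery studies and the null-contrast simulation — in
about a minute, while the block partition, the balancing arithmetic and
the statistical primitives are additionally verified at full scale
(60,483 features, 100 blocks) where the computation is exact and cheap.
Known limitations: performance numbers on real cohorts depend on data
the package does not ship; the binary decomposition cannot see
multi-organ interaction features; and the semantic clustering is a
simplified stand-in, suitable for grouping, not for reproducing published
similarity scores.
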