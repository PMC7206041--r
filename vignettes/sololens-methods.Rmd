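---
title: "Methods: single-subject dysregulation calling and network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-subject dysregulation calling and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sololens)
```

This vignette documents the statistical model behind `sololens`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic benchmarks do and do not demonstrate.

## The single-subject model

The input is one paired profile: raw counts for the same subject untreated
(`U`) and treated (`T`), with no replicates. The inferential trick is to
move the unit of analysis from the gene to the genome-wide distribution of
fold-change magnitudes.

**Normalization.** Default is upper-quartile: each sample is divided by the
75th percentile of its nonzero counts, then rescaled by the mean of the two
factors so values remain count-like. For a two-sample pair this is robust
(it ignores zeros and is insensitive to a handful of extreme genes) and
free of gene-length assumptions. `total_count` and `none` are selectable
via `normalizePair(method = )`. An all-zero sample is an error — there is
no meaningful scale factor for it.

**Fold changes.** `lfc = log2((T + c)/(U + c))` with pseudocount
`c = 0.5` (configurable), so every gene is finite, including U- or T-only
genes. We store the *signed* value oriented treated-over-untreated —
positive means induced by treatment — and its absolute value `|lfc|`,
which is identical under either orientation of the ratio.

**Mixture.** `|lfc|` is modelled as a two-component Gaussian mixture fitted
by EM: a component near zero for unaltered genes and a wider, shifted one
for dysregulated genes. Three output groups (up, down, unaltered) come from
two components plus the sign of `lfc` — one decision boundary on the
magnitude instead of two on the signed scale, which keeps the model
identifiable when up- and down-regulation are asymmetric in count. A gene
is called dysregulated when its posterior for the larger-mean component
exceeds 0.5 (configurable), and `lfc = 0` stays unaltered regardless — the
tie rule for genes whose magnitude is literally zero.

Numerical choices in the EM:

* means initialized at the 50th and 95th percentiles of `|lfc|`; weights
  and variances from a nearest-mean hard assignment. This is deterministic,
  so fits are reproducible without any RNG.
* convergence when the log-likelihood gain drops below `1e-8` (or 1,000
  iterations); the trace is stored and is non-decreasing, which the test
  suite asserts.
* a fit is declared degenerate when a component's standard deviation falls
  below `1e-6`, its weight below `1e-4`, or the data have fewer distinct
  values than components. Degenerate fits fall back, with a warning, to an
  all-unaltered call: with no separable tail there is no evidence of
  dysregulation, and a conservative answer is preferable to a collapsed
  likelihood.

Note the mixture is a working model, not a claim about the data-generating
process: `|lfc|` of null genes is folded-normal-like, not Gaussian. In
practice the fitted near-zero component absorbs that shape; on idealized
draws from `0.9·|N(0, 0.2)| + 0.1·|N(2.5, 0.4)|` the EM recovers the tail
weight to within ±0.03 and its mean to within ±0.2 (and agrees with an
independent mixture implementation, `mclust`, to the same precision), which
the acceptance tests verify.

## Pathway enrichment

Each gene set is reduced to a 2x2 table over the measured universe:
dysregulated (up ∪ down) vs unaltered, in-set vs out-of-set. Counting both
directions together targets *bidirectional* dysregulation — pathways
containing both induced and repressed members, which direction-specific
statistics miss. The test is the one-sided (greater) Fisher's exact test,
i.e. the hypergeometric right tail; the odds ratio is the sample estimate
`ad/bc` (`+Inf` when `bc = 0`, `0` when `ad = 0` with `bc > 0`).

Defaults and rationale:

* the universe is the measured genes, not the whole genome: the question is
  whether a set is enriched among genes we could have called.
* sets with fewer than 5 measured members are skipped — exact tests on
  smaller margins are uninformative and only dilute the correction.
* adjustment is Benjamini–Yekutieli over all sets tested in one batch (one
  batch per time point when several are analyzed). Overlapping sets make
  the p values dependent in an uncontrolled way; BY pays a `log m` factor
  for validity under arbitrary dependence. Separate up-only/down-only
  p values are available behind `directional = TRUE` but off by default.

## DEG selection

From an external cohort table (`gene_id`, `log2fc`, `p_adj`), DEGs are
`|log2fc| > 1` and `p_adj < 0.05` (both strict). From the single-subject
classification, where no per-gene p value exists, DEGs are genes called up
or down with `|lfc| > 1`. Both thresholds are configurable.

## Network construction, hubs, clusters

**Construction.** Interactions with combined score strictly greater than
700 (the conventional STRING high-confidence cut; strict because the rule
is "score > 700") are retained, optionally requiring a positive
experimental/database evidence channel. Nodes are the DEG seeds found in
the table plus, under the default `first_shell` policy, their direct
interactors; edges are *all* retained interactions among included nodes,
weighted by the combined score. First-shell expansion is the default
because seed lists of a few hundred genes typically recruit an order of
magnitude more interactors, and the recruited neighbourhood is where
complexes and signalling modules become visible; `seeds_only` is available.
Seeds absent from the table, or with no surviving edge, stay in the network
as isolated nodes and are reported — silently dropping them would bias
every downstream degree statistic.

**Hubs.** Top decile of unweighted degree: `k = ceiling(0.10 n)` nodes,
ranked by degree descending with deterministic id tie-breaking. Degree is
unweighted because "highest-degree nodes" is a connectivity notion;
weighting by confidence would conflate evidence strength with topology.

**Clusters.** Overlapping groups are grown greedily under the cohesiveness
score `f(V) = w_in / (w_in + w_bound + p·|V|)`: starting from the
highest-degree unused node, the single move (add a boundary vertex or
remove an internal non-seed vertex) with the largest score increase is
applied until a local maximum. Used nodes may be re-entered by later
growths, so clusters overlap. Clusters smaller than 3 nodes or with
unweighted edge density below 0.5 are discarded; pairs with overlap
`omega > 0.8` are transitively merged and re-scored. All tie-breaks are by
node id, making the procedure deterministic.

The penalty `p = 2` models unobserved interactions and is calibrated for
edge weights on the 0–1 probability scale (or unit weights). Raw STRING
combined scores are two to three orders of magnitude larger, which makes
the penalty negligible and lets greedy growth leak across low-confidence
bridges. In this package that is immaterial *when the standard score
threshold is applied first* — clustering operates on the
high-confidence network — but users clustering unthresholded score-weighted
graphs should raise the penalty accordingly (or rescale weights). The
planted-partition benchmark in the test suite documents this: with the
`> 700` filter in place, all five planted communities are recovered at
Jaccard 1.0.

**Significance.** Per cluster, each vertex contributes an internal weight
sum (to members) and a boundary weight sum (to non-members); a one-sided
Mann–Whitney U test asks whether internal stochastically dominates
boundary. For group sizes up to 20 the exact U distribution is used (ties
resolved by midranks), above that the normal approximation with tie and
continuity correction; when every pooled value is tied the test returns 1
(no evidence). The exact-by-size rule matters at the small end: a size-3
cluster can at best reach `p = 1/C(6,3) = 0.05`, so it is never flagged at
the 0.05 threshold — a property the tests assert. Clusters with `p < 0.05`
are flagged significant.

## Functional enrichment of hubs and clusters

`enrichGeneSet()` reuses the identical hypergeometric core on a query set
(hubs, or one cluster's members) against a GMT collection. The default
universe is every gene annotated in the collection — the natural reference
when the collection represents the annotation source — with the network as
an alternative universe left to the caller. Per the common practice for
screening GO terms, the default is *uncorrected* `p < 0.05` flags; because
uncorrected GO scans are anticonservative, BH and BY are selectable and the
flag then uses the corrected value.

## The synthetic generators

`simulatePairedCounts()` emulates the paired design: per-gene baseline
means drawn log-uniformly over `exp(log 20 … log 2000)` (spanning
low-count, noisy genes through well-measured ones), negative-binomial
counts with a shared dispersion of 0.1 (a typical bulk RNA-seq magnitude;
the minimal standard count model), a global 1.3-fold library-size imbalance
on the treated sample to exercise normalization, and dysregulation effects
`delta = ±|N(2.5, 0.4)|` log2 units with equal up/down probability. Ten of
100 pathways (30–50 genes each) are implanted at 50% member dysregulation
against a 5% background — background noise is the regime the bidirectional
test is meant to tolerate. These defaults are the package's reference
study conditions; all are configurable but the defaults are not tuned
per-analysis.

`simulateInteractome()` plants `k` communities of equal size in an
Erdős–Rényi background (`p_in` within, `p_out` between), with community
edges scored 701–999 and background edges 150–700, mirroring how true
complexes sit above and noise below the confidence threshold.

What the generators deliberately do **not** model: gene-length effects,
GC/batch artefacts, correlated expression within pathways (genes are
dysregulated independently given membership), gene-specific dispersions,
hub-dominated degree distributions, or score-dependent edge truth. Passing
the recovery benchmarks therefore shows the chain is *correct and
well-calibrated under its own assumptions* — not that it matches any
particular real dataset's operating characteristics. On real single-subject
data the false-positive rate of the gene-level calls is unknowable without
replicates; the pathway-level test is the intended readout precisely
because it is robust to a diffuse background of spurious calls (on the
reference conditions, gene-level F1 is ~0.6 while all ten implanted
pathways rank in the top 15 with ≥ 90% of null pathways non-significant).

## Pipeline determinism and problem sizes

`runPipeline()` chains simulate → ssa → degs → network → enrich under one
config; the single seed fans out to stage seeds by fixed offsets so stages
are independently reproducible, and the manifest records an MD5 digest per
output file — two runs with the same config must produce identical digest
vectors, which the test suite asserts on the bundled demo. The demo and the
test fixtures are sized to run in seconds-to-minutes on one core (demo: 500
genes, 20 pathways, 200-node interactome; reference conditions: 5,000
genes, 100 pathways; community benchmark: 100 nodes, 5 communities of 10);
the statistical behaviour of every component is scale-free in those sizes.

## Known limitations

* The mixture assumes a unimodal dysregulated tail; multi-modal effect
  sizes (e.g. distinct strong/weak regulons) are absorbed into one
  component and the posterior threshold loses its calibration.
* Single-subject calls carry no per-gene error control; downstream DEG
  lists should be read as ranked candidates, not discoveries.
* Identifier mapping between gene and protein namespaces is the caller's
  responsibility (an alias map TSV is supported; the default is identity).
* Cohesiveness-based clustering is a local search; it is deterministic but
  not globally optimal, and its penalty is weight-scale dependent (see
  above).
* The functional-enrichment default (uncorrected 0.05) mirrors common
  screening practice and is anticonservative by construction; corrections
  are one flag away.
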