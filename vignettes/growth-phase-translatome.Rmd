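---
title: "Models and methods: transcription-translation interplay across growth phases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: transcription-translation interplay across growth phases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboshift)
```

# Scope

`riboshift` analyses how transcription and translation are jointly
reorganized when a microbial culture moves from active growth into
stationary phase. It starts from gene-by-sample count tables of paired
RNA-seq (transcript abundance) and Ribo-seq (ribosome footprints) over an
ordered series of time points with replicates, plus three optional side
inputs: protein intensities of the ribosome-enriched fraction, a binary
gene-by-corem membership matrix from an ensemble regulatory-network model
with an expression compendium, and a bait-prey protein-interaction edge
list. Every stage is a plain function over validated tab-separated tables;
`run_all()` chains them, and `make_fixture()` emits a complete synthetic
input set with planted ground truth.

# The differential stage ("DE-lite")

The contrast of interest is the last time point against the first (e.g.
stationary versus early exponential). Counts are normalized by
median-of-ratios size factors; the gene-wise negative-binomial dispersion
is estimated by method of moments from the pooled within-group variance and
shrunk 50/50 toward a trend `a + b / mean` fitted across genes. The Wald
statistic on the log2 fold change (with a symmetric pseudocount of 0.5)
is referred to a moderated t distribution whose degrees of freedom credit
the across-gene trend with twice the gene-wise residual df — 12 df for
triplicates. With the 50/50 shrinkage this reference keeps the null
false-positive fraction at nominal level in the calibration test, whereas a
plain t(4) is severely conservative and a normal reference slightly
liberal. Benjamini-Hochberg adjustment runs across tested genes only;
genes whose mean normalized count falls below `min_mean_count` (default 1)
receive `NA` adjusted p-values and surface downstream as `NOT_ASSESSED`.
This stage deliberately emulates the role a full shrinkage-based NB fit
plays in practice: `import_differential()` accepts an externally produced
results table with the same columns, so the bespoke downstream analyses
can run unchanged on output of any differential engine.

# Regulatory classes

With `sig(x) := |log2FC| > 1 and padj < 0.05` (both thresholds
configurable), each gene falls into exactly one class:

| mRNA | footprints | same sign | class |
|------|------------|-----------|-------|
| sig  | sig        | yes       | `TC+` / `TC-` (transcriptional; footprints track transcripts) |
| sig up | not sig  | —         | `COMP-` (buffered induction) |
| sig down | not sig | —        | `COMP+` (buffered repression) |
| not sig | sig     | —         | `TL+` / `TL-` (translational only) |
| not sig | not sig | —         | `NR` |
| sig  | sig        | no        | `DISCORDANT` |
| any `NA` padj | | |           | `NOT_ASSESSED` |

`DISCORDANT` never occurs in the source analyses' vocabulary; we surface
it rather than silently mis-binning so that the labels stay a total,
deterministic function of the four statistics.

# Translational efficiency

TE is the log2 ratio of footprint TPM over mRNA TPM, computed from
within-time-point replicate medians (median rather than mean for
robustness to a single outlying replicate; configurable). Genes with zero
abundance in either assay get `NA` TE and leave the regression. The
headline fit is ordinary least squares of TE on `log10(TPM + 1)` at the
reference time point — per-time-point fits are the default because the
abundance-efficiency coupling strengthens with growth phase, and pooling
time points would blur that. Residuals are each gene's deviation from the
TE expected at its expression level; they feed two analyses:

* **Binned group tests.** Within half-open abundance bins
  (10, 100], (100, 1000], (1000, 10000] TPM, residuals of
  transcriptionally up- versus downregulated versus non-differential
  genes are compared by two-sided Mann-Whitney U tests (exact enumeration
  for eight or fewer observations without ties, normal approximation with
  tie and continuity correction otherwise). Bins with fewer than three
  genes on a side are reported untestable rather than tested.
* **Permutation abundance null.** A gene set's mean abundance is compared
  with `n_perm` uniformly drawn same-size gene sets;
  `p = (#{null <= observed} + 1) / (n_perm + 1)` for the lower tail. The
  lower tail is the default because the scientific claim is that
  translationally upregulated transcripts sit *below* the abundance
  expected by chance; the plus-one correction keeps the p-value valid and
  bounded away from zero.

Prediction-interval outlier calls (`prediction_interval_outliers()`) flag
genes whose footprint fold change escapes the 95% prediction band of the
OLS fit against the transcript fold change — single-gene exceptions to an
otherwise proportional relationship.

# Ribosomal-protein stoichiometry

Per protein and time point, the log2 fold change is the replicate-median
intensity over the replicate median at the reference; zeros propagate as
`NA` because data-independent-acquisition dropouts are informative and
imputation would manufacture stoichiometry. The stoichiometry ratio (SR)
subtracts, per time point, the median fold change across all detected
proteins — the "collective trend" of the assembled-ribosome fraction — so
the per-time-point median SR is identically zero. A deviation event is an
SR outside the central 95% interval of the cross-protein SR distribution;
a protein with two or more events across non-reference time points is
flagged.

The interval estimator is the one genuinely open design point in this
module. A raw percentile interval of the observed SR distribution is
widened by the very deviants it is meant to catch: with five planted
deviants among fifty proteins, the 2.5% quantile lands *between* the
deviant SRs and the sensitivity for a |SR| = 0.35 deviant collapses to
roughly 60%. The default is therefore a robust central interval,
`median ± z * 1.4826 * MAD`, a resistant estimate of the null SR spread;
the raw percentile interval remains available via
`flag_deviant_rps(interval = "percentile")`. With the robust interval the
detection test recovers planted deviants of |SR| ≥ 0.35 at two time points
in at least 90% of noise draws at replicate sd 0.1, while a |SR| ≈ 0.30
deviant remains borderline, and the null flag rate stays at the few-percent
level. Because the reference-time-point noise is shared across a protein's
fold changes, false flags are positively correlated across time points;
this is a property of the ratio design, not of the interval.

# Corem classes and condition-specific similarity

Genes are clustered on their binary corem-membership profiles with the
asymmetric binary (Jaccard) dissimilarity — mismatches over corems
containing at least one of the two genes — and average-linkage (UPGMA)
clustering; genes in no corem are excluded. Cluster confidence comes from
an ordinary bootstrap: corems (columns) are resampled with replacement
`n_bootstrap` times (default 10000) and each observed clade is scored by
the fraction of resampled trees containing it (bootstrap probability, BP).
The multiscale "approximately unbiased" correction is deliberately not
implemented: BP is well defined, directly testable, and on the block
structures at issue the two agree closely; the class-selection threshold
keeps its ≥ 0.95 semantics. Classes are the maximal supported clades —
supported clades not contained in a larger supported clade, excluding the
root and singletons — labelled by decreasing size; uncovered genes are
`unassigned`.

Two numerical details matter. First, within each bootstrap replicate the
gene order is randomly permuted before clustering, so that exactly tied
distances (ubiquitous in noise-free block structures) are broken uniformly
at random rather than by input order; without this, arbitrary superset
clades inherit full support and swallow the real classes. Second, a gene
that loses all membership in a resample is an all-zero profile; pairs of
such genes get distance 0 (identical profiles) and distance 1 to everyone
else.

The supports of small classes sit near the threshold by nature: at a
membership flip rate of 0.05 the exact-clade BP of a 3-gene class
fluctuates across noise realizations, so the full four-class structure is
recovered in a majority but not all draws, while the adjusted Rand index
of the partition against the planted one stays at or above 0.9 (this is
the invariant the acceptance test asserts, and why the acceptance script
reports medians over five generator replicates).

Corem expression signatures are per-condition medians (with IQR) across
member genes. Two corems are "similar" — no significant expression
difference — when Spearman's rank correlation exceeds 0.4 with p < 0.05
and a two-sample Kolmogorov-Smirnov test is non-significant (p > 0.05);
rank correlation captures shape, the KS test catches level shifts, and a
constant signature leaves the decision `not similar, degenerate`. Class
similarity within a condition category is the proportion of similar corem
pairs, one corem from each class, excluding self-pairs within a class (so
diagonals need not reach one). The mapping from corems to classes is not
dictated by the inputs; a corem is assigned to the class holding the
majority of its labelled member genes, with ties dropped.

# Interaction-network modules

Bait-prey records are deduplicated into a directed graph (self-loops kept
and reported). Community detection runs Girvan-Newman — iterative removal
of the highest-edge-betweenness edge — on the undirected simple
projection, cut at the global modularity maximum over the removal
sequence. Direction is preserved for reporting only, in particular for
extracting edges from transcription-machinery baits (TBP, TFB, Bat) to
ribosomal-protein prey with per-role and per-subunit counts. Note that a
divisive algorithm only ever sees the partitions its own removal sequence
induces; the globally modularity-optimal partition of an arbitrary graph
need not be among them, which is an inherent property of the method, not a
defect of the cut rule.

# The synthetic-data generator

The generator plants known truth so that every stage is testable without
external data. What it emulates, and what it does not:

* **Paired counts.** Baseline abundance is log-normal
  (log10 TPM ~ N(2, 0.6), spanning the three analysis bins); regulated
  classes draw |log2 FC| ~ U(1.5, 3) and null directions U(-0.25, 0.25);
  time-course effects interpolate log-linearly between the first and last
  time point, since the analysed contrasts are endpoint-to-endpoint and
  intermediate points only need plausible monotone trends. The TE line
  (slope -1.10 per log10 TPM unit, intercept 2.2) plus a per-gene TE
  offset (sd 1.0 log2 units) is applied to the footprint mean at the
  reference time point, and footprint means then scale by the planted
  footprint fold change — so the planted slope and the planted fold
  changes are both exact on the mean scale, making parameter recovery a
  clean oracle. The TE offset sd of 1.0 is what makes the synthetic
  TE-abundance correlation land near -0.5 rather than an unrealistic -1.
  Counts are negative-binomial with a shared dispersion (default 0.02,
  typical of tight triplicate batch cultures; the classification stress
  test runs at 0.05) and library size 5e6. Translationally upregulated
  genes draw their abundance 0.8 dex low, mirroring their observed
  low-abundance character; `NOT_ASSESSED` genes sit far below the count
  floor (log10 TPM ~ N(-2.5, 0.3)), emulating unquantifiable genes.
  Count noise enters both the TE response and the abundance covariate, so
  the OLS slope carries an errors-in-variables bias of order
  `-(log2(10) + a) * Var(x_noise) / Var(x)`; at the default dispersion
  with replicate medians this is about a third of the slope's standard
  error, which is why nominal CI coverage still holds in the recovery
  test. The generator does not emulate gene length variation (TPM is
  computed with unit lengths), operon structure, or between-replicate
  batch effects.
* **Proteomics.** Log2 intensities follow a per-time-point global trend
  (default ending at -1.04) plus planted per-protein SR offsets and
  replicate noise (sd 0.1). No peptide-level structure or
  intensity-dependent dropout is simulated.
* **Corems.** Block-diagonal membership (default classes 38/7/6/3 over 72
  corems, block widths proportional to class sizes with a floor of six)
  with independent bit flips; the compendium gives each class a shared
  per-condition response (sd 1.5) plus gene noise (sd 0.4) over 135
  conditions in 9 categories — a deliberate scale-down of a
  1495-condition compendium that preserves the similarity structure, not
  its dimensionality.
* **Interactions.** A planted partition (126 nodes, 7 modules,
  p_in = 0.8, p_out = 0.05) with every node eligible as bait by default;
  a bait-restricted mode (k baits per module, edges only from baits)
  mimics a tagged-bait immunoprecipitation screen at study scale
  (128 nodes, 14 baits, a couple hundred edges).

Passing tests on these fixtures demonstrates that the statistics recover
what was planted under the stated noise models; they cannot certify
behaviour under real-data pathologies the generator omits (length biases,
batch effects, correlated dispersions, peptide-level artefacts).

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `fc_threshold` | 1 | log2 | regulated-gene magnitude filter |
| `alpha` | 0.05 | — | significance level throughout |
| `n_permutations` | 1e6 | draws | abundance permutation null |
| `n_bootstrap` | 1e4 | resamples | clade support |
| `ci_level` | 0.95 | — | prediction / SR intervals |
| `min_deviation_events` | 2 | events | SR flagging |
| `srcc_threshold` | 0.4 | — | corem similarity |
| `abundance_bins` | 10, 100, 1000, 10000 | TPM | binned residual tests |
| `min_mean_count` | 1 | normalized counts | assessment floor |
| `random_seed` | 1 | — | fans out per stage via `stage_seed()` |

Every stochastic operation takes an explicit seed; a single configured
seed is hashed with the stage name so each stage reproduces independently
of execution order.

# Problem sizes in the test-suite

The test suite and the acceptance script run everything at desk scale:
2663-gene universes for classification and TE recovery, 100-seed coverage
simulations at 2000 genes, 1e4-draw permutation calibrations over 200
sets, 1000-resample bootstraps for the 54-gene corem fixture, and
20-seed planted-partition recoveries — sizes chosen so each property is
measured with useful precision while a full run stays in the minutes
range on one core. The package defaults (`n_permutations = 1e6`,
`n_bootstrap = 1e4`) match the scale a real analysis would use.

# Known limitations

* DE-lite is a deliberately simple emulation of a shrinkage-based NB fit:
  no fold-change shrinkage, no covariates, two-group contrasts only. Slot
  in external results via `import_differential()` when exactness matters.
* The SR interval assumes most proteins follow the collective trend;
  if a majority deviated, median-centering itself would absorb the signal.
* Exact-clade bootstrap support is intrinsically brittle for very small
  classes under membership noise (see above); judge recovery by the
  partition ARI as well as the class count.
* Girvan-Newman is greedy; on graphs without clear community structure
  its max-modularity cut can score below the exhaustive optimum.
* The permutation p-value counts ties (`null <= observed`), so for a
  degenerate set equal to the whole universe it is exactly 1, and its
  minimum value 1/(n_perm+1) is attained only when no null draw ties the
  observed set.
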