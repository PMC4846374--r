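---
title: "Methods: cell-class- and region-specific analysis of hippocampal bulk RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-class- and region-specific analysis of hippocampal bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoexpr)
```

`hippoexpr` analyses sorted-population bulk RNA-seq of hippocampal
excitatory neurons profiled by cell class (dentate granule cells GC, hilar
mossy cells MC, pyramidal cells of CA3, CA2, CA1) and, for the
trisynaptic-loop classes, by dorsal/ventral region — eight populations in
all, each with biological replicates. The package starts from a genes ×
samples FPKM matrix; alignment and quantification are upstream and out of
scope. This vignette records the models, the parameters that matter, what
the synthetic generator does and does not emulate, and the design decisions
taken where the procedure left genuine choices.

## Data model

An expression matrix is a dense tibble of non-negative, finite FPKM with a
character `gene_id` key; gene identifiers are opaque strings (no mapping is
attempted). Metadata assigns each sample a cell class, a region (`dorsal`,
`ventral`, or `none` for MC and CA2, which are profiled without a regional
split) and a replicate index; a (class, region) pair defines a population.
`aggregate_replicates()` produces the population matrix of arithmetic-mean
FPKM used by every population-level rule. Text I/O is TSV (CSV selectable)
with values serialized to 6 significant digits, matching common
quantification-tool output precision; loading a written matrix reproduces
it to that precision.

## Quality control

Replicate reproducibility is the all-pairs Pearson correlation of
whole-transcriptome FPKM vectors within each population; a population
passes only when every pair exceeds 0.90. The all-pairs reading is the
strictest of the possible per-class gates and is recorded in the report. We
correlate raw FPKM by default (the scale on which replicate scatter is
conventionally displayed); a log option exists. A zero-variance replicate
vector leaves the correlation undefined and is treated as a failure rather
than silently dropped. The same machinery restricted to the ERCC-like
spike-in block measures quantification fidelity, and spike-ins are excluded
from all downstream analyses. The contamination check flags any sample in
which an interneuron or non-neuronal panel gene (Gad1, Gad2, Sst, Pvalb,
Vip, Gfap, Aqp4, Mbp, Plp1, Cx3cr1, Aif1, Cldn5 by default) exceeds the
expressed-gene cutoff of 10 FPKM; no separate purity threshold is defined,
so the expression cutoff is reused.

## Marker rules

All rules act on genes passing the expressed filter — population-mean FPKM
strictly above 10 in at least one population — and all are scale-free
(multiplying the matrix by a positive constant changes no call).

* **Mean X-fold rule** (class markers, X = 3): called iff
  `min(target means) ≥ X · max(off-target means)`. The boundary is closed
  (≥) by default because the operative definition is "at least X-fold"; a
  strict switch exists since "more than X-fold" is also in circulation for
  the same rule. The achieved fold `min(target)/max(off-target)` is
  reported, `Inf` when all off-target means are zero (zero-handling is
  otherwise unspecified; infinite folds sort first).
* **Per-replicate rule** (dendrogram-branch markers, fold 2): every target
  replicate at least 2 × every individual non-target replicate — the
  strictest reading of "every replicate versus the remaining samples"; a
  mean-of-rest variant is available behind a flag.
* **Pole rule** (regional enrichment, fold 2): within one class, dorsal
  mean ≥ 2 × ventral mean (and symmetrically), among genes expressed in at
  least one of the class's two pole populations. The two lists are disjoint
  whenever fold > 1.

## Transcriptome structure

Profiles are `p_g = log10(FPKM_g + 1) / Σ log10(FPKM_g + 1)` per sample; an
all-zero sample is an error naming the sample. The Jensen–Shannon
divergence uses base-2 logarithms with `0·log 0 = 0`, and the distance is
its square root — the standard choice that makes it a metric bounded by
[0, 1]; the base and the root are conventions we fix and state, since
either choice only rescales the tree. Clustering is complete-linkage
agglomeration (`stats::hclust`), whose merge heights are provably monotone;
population-averaged profiles are used for the whole-dataset dendrogram and
replicate-level profiles for ordination, and both entry points are exposed.
Classical MDS is Torgerson double-centering via `stats::cmdscale`; because
the embedding is unique only up to rotation and reflection, each axis is
flipped so its first nonzero loading is positive, making output
deterministic. When fewer than `k` positive eigenvalues exist the missing
coordinates are zero-padded. Heat-map display divides each gene by its
maximum across samples, with all-zero genes left at zero.

## Regional overlap and its Monte Carlo null

For a set of classes, the observed statistic is the size of the
intersection of their same-pole enriched lists. The null redraws, for each
class, as many genes as its enriched list, uniformly without replacement
from that class's **own** expressed universe — universes may differ in size
and content, which is why the null is simulated rather than taken from a
single hypergeometric formula; for two classes sharing one universe it
reduces to the hypergeometric law with mean `n₁n₂/N`, the closed form used
as the test oracle. Dorsal and ventral poles are tested separately and
also summed into a combined count; all three are reported.

Two p-values are emitted deliberately: the add-one empirical estimator
`(1 + #(null ≥ obs))/(1 + n_reps)`, reported as an upper bound
(`< 1/(n_reps+1)`) when no null draw reaches the observation, and a
normal-approximation upper tail from `z = (obs − mean)/sd`. A finite
replicate count floors the empirical p (1000 replicates cannot certify
p below ~1e-3), so neither estimator is chosen over the other. Draws are
seeded per (pole, replicate, class), making results bit-reproducible and
independent of evaluation order. `directional_concordance()` compares the
internal pole-enriched lists against an external differential-expression
list (gene, pole), counting same-direction matches; conflicting duplicate
entries in the external list are an error rather than a silent vote.

## Co-expression modules

Module detection follows the simplified correlation scheme rather than full
WGCNA (no soft-thresholding, topological overlap or eigengenes): select the
1000 most variable genes, correlate, transform, cluster divisively.
Decisions taken here:

* *Variance scale.* Variance is computed on `log10(FPKM+1)` of population
  means; raw-FPKM variance would be dominated by the highest expressors. A
  raw-scale flag exists.
* *Expression floor.* `FPKM_MIN = 5` is read as the minimum across
  populations being at least 5 (the symbol names a minimum); a max-based
  reading is selectable.
* *Correlation across datasets* uses the 8 population means, not the 24
  replicates; a replicate-level mode exists.
* *Dissimilarity* is the affine map `D = 1 − (C + 1)/2`, the unique
  reading of the transform that sends correlation 1 to 0 and −1 to 1.
* *DIANA* is implemented from its definition (largest-diameter cluster
  split by a splinter group seeded at the object of maximal average
  dissimilarity, objects moving while they prefer the splinter), with
  lowest-index tie-breaks so trees are deterministic; split heights are the
  diameters of the clusters split, and the result is an `hclust`-compatible
  object. The reference implementation in the `cluster` package serves as
  an independent cross-check in the tests, never as the implementation.
* *Cutting.* Absolute cut heights do not transfer between divisive-tree
  height conventions, so the default cut targets a requested module count
  (8 by default) with an absolute-height mode for calibrated pipelines.
  The module count is an output to inspect, not a constraint.

Module profiles are per-population means of members' max-normalized
expression. `gene_set_test()` provides a one-sided hypergeometric
enrichment test with Benjamini–Hochberg adjustment across annotation sets —
deliberately a generic stand-in for web-service annotation tools, not a
reimplementation of one.

## The synthetic generator

`simulate_dataset()` emulates the study design: 8 populations × 3
replicates, per-gene baseline FPKM drawn log10-normal (mean 1.0, sd 0.8 on
the log10 scale — a median of 10 FPKM with a realistic bulk dynamic range),
and mean-one multiplicative lognormal replicate noise. The noise scale
(`replicate_cv = 0.14`) is the closed-form value at which two replicates
sharing lognormal gene means correlate at ~0.98 on raw FPKM, the
reproducibility regime the QC gate expects of good sorted-population data;
the spike-in noise (`cv = 0.25`) likewise targets the ~0.94 regime typical
of spike-in quantification. Planted structure multiplies population means
*before* noise, so noiseless folds are exact and recovery tests have exact
ground truth:

* class markers (defaults: 300 GC genes at fold 10, 200 MC at 8, 100 each
  for CA3/CA2/CA1 at 5) — ordered so the dendrogram's planted hierarchy is
  GC versus the rest, then MC versus pyramidal cells, then dorsal–ventral
  within classes, the ordering expected of hippocampal transcriptomes;
* region genes (30 per pole shared across GC/CA3/CA1 at fold 3, plus 80
  per pole per class), implemented as pole multipliers;
* eight co-expression modules (40 genes each) with population-profile
  multipliers shaped like the biological groupings (GC, MC, per-CA-field,
  pyramidal, dorsal, ventral);
* a deterministic spike-in concentration ladder (92 genes, 10^−1 to 10^3)
  shared by all samples; and a contamination panel at exactly zero FPKM
  unless leakage is configured, in which case randomly chosen samples
  express the panel at `leakage × source_fpkm` and are recorded in the
  manifest.

Planted differential genes receive a baseline floor of 15 FPKM: a planted
marker below the expressed filter would be undetectable by construction,
and real reported markers are expressed by definition. Background genes
have identical means in every population, so *all* between-population
structure is planted and the manifest (one role per gene) is a complete
ground truth. One integer seed drives independent derived streams for
baseline, noise and contamination, so the same seed is bit-reproducible
and adding a planted feature never perturbs background draws.

What the generator does **not** emulate: count-level (negative binomial)
sampling and mean–variance coupling, batch effects, gradients sampled at
more than two points along the long axis, correlated background genes, and
library-size artefacts. Passing recovery tests therefore demonstrates that
the rules and algorithms do what they claim on data with known structure —
not that real tissue meets the generator's assumptions.

## Numerical choices and degenerate inputs

Boundary and degenerate behaviour is pinned down by tests: the expressed
filter is strictly greater-than (a gene at exactly 10 FPKM is excluded);
fold rules are closed at the threshold by default; folds against zero are
`Inf`; all-zero samples error in the profile transform; all-zero genes
normalize to zero in heat maps; zero-variance genes are dropped (with a
warning) before gene–gene correlation; a cut below every split height
yields singletons and a cut above the root one module; empirical p-values
never return 0. Agglomeration and DIANA break ties toward the lowest
index. The JS distance closed form `d((1,0),(½,½)) = 0.557923` and the
hypergeometric null moments (mean 6.0, sd 1.842 at N = 100, draws 20/30)
are verified to 1e-6 and Monte Carlo precision respectively.

## Problem sizes used in the tests

The suite exercises the full 5000-gene, 24-sample design where the claim
depends on it (hierarchy recovery over 10 seeds, calibration of replicate
correlation) and smaller planted designs (400–2000 genes) elsewhere, chosen
so the whole suite completes in well under a minute of compute while every
statistical assertion retains at least 3-sigma Monte Carlo headroom. The
overlap null is checked at 20,000 replicates against its closed form and at
50,000 replicates against an exhaustive triple-draw enumeration at N = 12.

## Known limitations

The pipeline starts from FPKM and inherits its length-normalization
caveats; no FDR-based differential expression is provided (fold-change
rules only); gene identifiers are not harmonized against external lists,
so directional-concordance inputs must share the internal naming; and the
Monte Carlo null treats classes' draws as independent, which is exactly
the chance model being tested but ignores any correlation in how real
enriched lists are derived from overlapping replicate sets.
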