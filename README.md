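# hippoexpr

Downstream analysis of cell-class- and region-specific bulk RNA-seq of
hippocampal principal neurons, as a tested, reusable R package.

The hippocampus contains five major excitatory cell classes — dentate gyrus
granule cells (GC) and mossy cells (MC), and pyramidal cells of CA3, CA2 and
CA1 — and the trisynaptic-loop classes (GC, CA3, CA1) differ along the
dorsal–ventral axis. Sorted-population bulk RNA-seq of these populations
(8 populations × 3 biological replicates) yields an FPKM matrix from which
marker genes, transcriptome-wide relationships, region-invariant gene
programs and co-expression modules can be derived. `hippoexpr` implements
that downstream analysis for anyone starting from a genes × samples FPKM
matrix plus sample metadata (cell class, region, replicate), and ships a
synthetic-data generator with a ground-truth manifest so every stage has a
recovery test.

## What it computes

* **Quality control** — all-pairs within-population Pearson correlation of
  replicate FPKM vectors (pass requires every pair r > 0.90), ERCC-style
  spike-in reproducibility, and a contamination check against an
  interneuron/glial marker panel.
* **Marker genes** — with population means `FPKM_g,p` and an expressed-gene
  filter (`FPKM > 10` in at least one population), three fold-change rules:
  * *mean X-fold rule*: gene `g` is an X-fold marker of target set `T` iff
    `min_{t∈T} FPKM_g,t ≥ X · max_{o∉T} FPKM_g,o` (X = 3 for class markers);
  * *per-replicate rule*: every target replicate ≥ 2 × every non-target
    replicate;
  * *pole rule*: within a class, dorsal list = `{g : FPKM_dorsal ≥ 2 ·
    FPKM_ventral}` and symmetrically for ventral.
* **Transcriptome structure** — per-sample probability profiles
  `p_g = log10(FPKM_g + 1) / Σ_g log10(FPKM_g + 1)`, the pairwise
  Jensen–Shannon distance `d(p,q) = sqrt(½KL(p‖m) + ½KL(q‖m))` with
  `m = (p+q)/2` and base-2 logs, complete-linkage agglomerative clustering,
  and classical (Torgerson) MDS.
* **Region-invariant genes** — counts of pole-enriched genes shared across
  classes, tested against a Monte Carlo null that draws each class's list
  size uniformly without replacement from that class's expressed universe
  (hypergeometric mean `n₁n₂/N` for two classes sharing one universe), plus
  directional concordance against an external dorsal–ventral gene list.
* **Co-expression modules** — the 1000 most variable expressed genes
  (FPKM_MIN ≥ 5), gene–gene Pearson correlation `C` across populations,
  dissimilarity `D = 1 − (C + 1)/2`, divisive (DIANA) hierarchical
  clustering implemented from its definition, and module profiles of
  max-normalized expression; a hypergeometric gene-set test annotates
  modules.

## Worked example

Everything below runs on a synthetic dataset whose planted structure is
recorded in a manifest; swap in `read_expression_matrix()` /
`read_sample_metadata()` for real files.

```r
library(hippoexpr)

sim  <- simulate_dataset(sim_config(seed = 42))
expr <- sim$expression   # 5000 genes x 24 samples, FPKM
meta <- sim$metadata     # sample_id, cell_class, region, replicate

qc_report(expr, meta)
#> QC report: 8 populations; 8 pass the all-pairs r > 0.9 gate
#> spike-in mean pairwise r: 0.94
#> contamination-flagged samples: 0

pop <- aggregate_replicates(drop_spike_ins(expr), meta)
length(expressed_genes(pop))
#> [1] 3373

head(mean_fold_markers(pop, "CA2", fold = 3), 3)
#> # A tibble: 3 x 5
#>   gene_id rule      target  fold target_mean_fpkm
#> 1 G01471  mean_fold CA2     6.69             103.
#> 2 G01476  mean_fold CA2     6.42             104.
#> 3 G01464  mean_fold CA2     6.32             104.

null <- monte_carlo_null(build_overlap_scenario(pop), n_reps = 1000, seed = 42)
tidy(null)[, 1:6]
#> # A tibble: 3 x 6
#>   pole     observed null_mean null_sd p_empirical p_empirical_label
#> 1 dorsal         70     0.328   0.565    0.000999 < 0.000999
#> 2 ventral        70     0.299   0.551    0.000999 < 0.000999
#> 3 combined      140     0.627   0.795    0.000999 < 0.000999
```

The QC block says all 8 populations reproduce (every replicate pair
r > 0.90) and no sample expresses the contamination panel. 3373 genes pass
the expressed filter; the CA2 marker table lists genes at least 3-fold
enriched in CA2 over every other population, with the achieved fold. The
overlap test finds 70 genes per pole enriched in the same direction in all
three trisynaptic classes, against a chance expectation of ~0.3 — the
planted region-invariant program, recovered as far beyond chance
(`p_empirical` is the add-one upper bound reachable with 1000 replicates;
`p_normal` gives the tail approximation).

`run_pipeline(pipeline_config(out_dir))` chains all stages and writes
delimited tables, a Newick dendrogram, JSON results and a checksummed
manifest; reruns with the same config and seed are byte-identical.

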