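# Shared fixtures and small independent oracles, all built in code.

# Minimal two-population, two-replicate design.
tiny_meta <- function() {
  tibble::tibble(
    sample_id = c("CA1_dorsal_1", "CA1_dorsal_2", "CA2_1", "CA2_2"),
    cell_class = c("CA1", "CA1", "CA2", "CA2"),
    region = c("dorsal", "dorsal", "none", "none"),
    replicate = c(1L, 2L, 1L, 2L)
  )
}

tiny_expr <- function(values = NULL) {
  v <- if (is.null(values)) {
    matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 3, 4)
  } else {
    values
  }
  tibble::tibble(gene_id = paste0("g", seq_len(nrow(v)))) |>
    dplyr::bind_cols(tibble::as_tibble(`colnames<-`(v, tiny_meta()$sample_id)))
}

# Uniform random point on the probability simplex (Dirichlet(1,...,1)).
rand_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# Generator config planting only class/region markers (no modules), for
# marker-recovery tests.
marker_cfg <- function(seed = 1, cv = 0, fold = 4, n_genes = 1500) {
  sim_config(
    n_genes = n_genes, seed = seed, replicate_cv = cv,
    class_markers = list(
      list(classes = "CA2", fold = fold, count = 40),
      list(classes = "MC", fold = fold, count = 40)
    ),
    region_genes = list(
      list(pole = "dorsal", fold = fold, count = 30, classes = "GC"),
      list(pole = "ventral", fold = fold, count = 30, classes = "GC")
    ),
    modules = NULL,
    contamination = list(genes = character(), leakage = 0, n_samples = 0),
    spike_ins = list(n = 0, cv = 0)
  )
}

# Generator config planting only co-expression modules: one module peaking in
# each of the eight populations.
module_cfg <- function(seed = 1, n_modules = 8, count = 40, mult = 5,
                       n_genes = 2000) {
  pops <- population_labels(
    tibble::tibble(sample_id = NA, cell_class = default_populations()$cell_class,
                   region = default_populations()$region, replicate = 1L)
  )
  mods <- lapply(seq_len(n_modules), function(i) {
    list(name = paste0("mod", i),
         profile = stats::setNames(mult, pops[i]),
         count = count)
  })
  sim_config(n_genes = n_genes, seed = seed,
             class_markers = NULL, region_genes = NULL, modules = mods,
             contamination = list(genes = character(), leakage = 0, n_samples = 0),
             spike_ins = list(n = 0, cv = 0))
}

# Exhaustive inclusion probabilities: for each of N genes, the probability of
# being included in a uniform draw of size k, computed by enumerating every
# subset with combn().
enum_inclusion_prob <- function(N, k) {
  subs <- utils::combn(N, k)
  vapply(seq_len(N), function(g) mean(apply(subs, 2, function(s) g %in% s)),
         numeric(1))
}

# Partition agreement (adjusted Rand index) between two labelings.
partition_agreement <- function(a, b) mclust::adjustedRandIndex(a, b)
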