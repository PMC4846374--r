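pop_fixture <- function(vals) {
  # vals: named list population -> numeric vector over genes
  dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", seq_along(vals[[1]]))),
                   tibble::as_tibble(vals))
}

test_that("expressed filter is a strict threshold on the max population mean", {
  pop <- pop_fixture(list(A = c(10, 0, 5), B = c(9, 0, 5), C = c(8, 11, 5)))
  expect_identical(expressed_genes(pop, 10), "g2")  # max exactly 10 excluded
  sim <- simulate_dataset(marker_cfg(seed = 8, cv = 0.2, n_genes = 2000))
  pm <- aggregate_replicates(sim$expression, sim$metadata)
  oracle <- pm$gene_id[apply(as.matrix(pm[, -1]), 1, max) > 10]
  expect_identical(expressed_genes(pm, 10), oracle)
})

test_that("mean-fold rule respects the closed boundary and zero handling", {
  pop <- pop_fixture(list(T = c(30, 29.9, 40, 5), A = c(10, 10, 0, 1),
                          B = c(9, 9, 0, 1), C = c(8, 8, 0, 1)))
  calls <- mean_fold_markers(pop, "T", fold = 3, expressed_threshold = 10)
  # 30 vs max 10 meets >= 3; 29.9 fails; 40 vs 0 gives fold Inf; 5 fails filter
  expect_setequal(calls$gene_id, c("g1", "g3"))
  expect_equal(calls$fold[calls$gene_id == "g1"], 3)
  expect_equal(calls$fold[calls$gene_id == "g3"], Inf)
  # Inf folds sort first
  expect_identical(calls$gene_id[1], "g3")
  strict <- mean_fold_markers(pop, "T", fold = 3, strict = TRUE,
                              expressed_threshold = 10)
  expect_false("g1" %in% strict$gene_id)
  expect_error(mean_fold_markers(pop, "T", fold = 1), "> 1")
  expect_error(mean_fold_markers(pop, c("T", "A", "B", "C"), fold = 3),
               "proper subset")
})

test_that("mean-fold calls are monotone in the fold and scale-free", {
  sim <- simulate_dataset(marker_cfg(seed = 12, cv = 0.2, n_genes = 800))
  pop <- aggregate_replicates(sim$expression, sim$metadata)
  lo <- mean_fold_markers(pop, "CA2", fold = 2)
  hi <- mean_fold_markers(pop, "CA2", fold = 3.5)
  expect_true(all(hi$gene_id %in% lo$gene_id))
  scaled <- pop
  scaled[, -1] <- scaled[, -1] * 7.3
  # scaling moves the expressed filter, so compare with the filter disabled
  a <- mean_fold_markers(pop, "CA2", fold = 3, expressed_threshold = NULL)
  b <- mean_fold_markers(scaled, "CA2", fold = 3, expressed_threshold = NULL)
  expect_identical(a$gene_id, b$gene_id)
  expect_equal(a$fold, b$fold)
})

test_that("noiseless planted class markers are recovered exactly", {
  sim <- simulate_dataset(marker_cfg(seed = 1, cv = 0, fold = 4))
  pop <- aggregate_replicates(sim$expression, sim$metadata)
  calls <- mean_fold_markers(pop, "CA2", fold = 3)
  expect_setequal(calls$gene_id, planted_genes(sim, "class_marker", "CA2"))
  mc <- mean_fold_markers(pop, "MC", fold = 3)
  expect_setequal(mc$gene_id, planted_genes(sim, "class_marker", "MC"))
})

test_that("per-replicate rule vetoes on a single failing replicate", {
  meta <- tibble::tibble(
    sample_id = c("t1", "t2", "t3", "o1", "o2"),
    cell_class = c("CA2", "CA2", "CA2", "CA1", "CA1"),
    region = c("none", "none", "none", "dorsal", "dorsal"),
    replicate = c(1L, 2L, 3L, 1L, 2L))
  expr <- tibble::tibble(gene_id = c("pass", "veto"),
                         t1 = c(21, 19), t2 = c(22, 40), t3 = c(25, 40),
                         o1 = c(10, 10), o2 = c(8, 9))
  calls <- per_replicate_markers(expr, meta, "CA2", fold = 2,
                                 expressed_threshold = NULL)
  expect_identical(calls$gene_id, "pass")   # 21 >= 2*10; veto: 19 < 20
})

test_that("per-replicate calls match an exhaustive all-pairs oracle", {
  sim <- simulate_dataset(marker_cfg(seed = 13, cv = 0.3, n_genes = 600))
  calls <- per_replicate_markers(sim$expression, sim$metadata, "CA2",
                                 fold = 2)
  m <- as.matrix(sim$expression[, -1])
  labs <- population_labels(sim$metadata)
  pop <- aggregate_replicates(sim$expression, sim$metadata)
  expr_set <- expressed_genes(pop, 10)
  oracle <- vapply(seq_len(nrow(m)), function(i) {
    t_v <- m[i, labs == "CA2"]; o_v <- m[i, labs != "CA2"]
    all(outer(t_v, o_v, function(a, b) a >= 2 * b)) && all(t_v > 0)
  }, logical(1))
  oracle_ids <- sim$expression$gene_id[oracle]
  expect_setequal(calls$gene_id, intersect(oracle_ids, expr_set))
})

test_that("pole enrichment splits genes into disjoint dorsal/ventral lists", {
  pop <- pop_fixture(list(GC_dorsal = c(40, 12, 11, 30),
                          GC_ventral = c(10, 11, 40, 0)))
  enr <- pole_enriched_genes(pop, "GC", fold = 2)
  expect_identical(enr$gene_id[enr$pole == "dorsal"], c("g4", "g1"))
  expect_identical(enr$gene_id[enr$pole == "ventral"], "g3")
  expect_equal(enr$fold[enr$gene_id == "g4"], Inf)
  expect_length(intersect(enr$gene_id[enr$pole == "dorsal"],
                          enr$gene_id[enr$pole == "ventral"]), 0)
  expect_error(pole_enriched_genes(pop, "CA2"), "missing pole")
})

test_that("noiseless planted region genes are recovered exactly", {
  sim <- simulate_dataset(marker_cfg(seed = 2, cv = 0, fold = 4))
  pop <- aggregate_replicates(sim$expression, sim$metadata)
  enr <- pole_enriched_genes(pop, "GC", fold = 2)
  expect_setequal(enr$gene_id[enr$pole == "dorsal"],
                  planted_genes(sim, "region_gene", "dorsal:GC"))
  expect_setequal(enr$gene_id[enr$pole == "ventral"],
                  planted_genes(sim, "region_gene", "ventral:GC"))
})
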