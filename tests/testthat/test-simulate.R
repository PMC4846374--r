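test_that("the generator is bit-reproducible and seed-sensitive", {
  cfg <- marker_cfg(seed = 9, cv = 0.14, n_genes = 300)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$manifest$genes, b$manifest$genes)
  c <- simulate_dataset(marker_cfg(seed = 10, cv = 0.14, n_genes = 300))
  expect_false(identical(a$expression, c$expression))
})

test_that("noiseless replicates are identical and planted folds exact", {
  cfg <- marker_cfg(seed = 2, cv = 0, fold = 4)
  sim <- simulate_dataset(cfg)
  m <- as.matrix(sim$expression[, -1])
  labs <- population_labels(sim$metadata)
  for (p in unique(labs)) {
    sub <- m[, labs == p, drop = FALSE]
    expect_equal(sub[, 1], sub[, 2])
    expect_equal(sub[, 1], sub[, 3])
  }
  # pairwise replicate correlation is exactly 1
  qc <- replicate_correlation(sim$expression, sim$metadata)
  expect_equal(qc$pairs$r, rep(1, nrow(qc$pairs)))
  # planted CA2 marker: CA2 mean is exactly 4x every other population mean
  pop <- aggregate_replicates(sim$expression, sim$metadata)
  ca2 <- planted_genes(sim, "class_marker", "CA2")
  pm <- as.matrix(pop[match(ca2, pop$gene_id), -1])
  ratios <- pm[, "CA2"] / pm[, setdiff(colnames(pm), "CA2")]
  expect_equal(unname(as.vector(ratios)), rep(4, length(ratios)))
})

test_that("background population means are exchangeable across populations", {
  sim <- simulate_dataset(marker_cfg(seed = 5, cv = 0))
  pop <- aggregate_replicates(sim$expression, sim$metadata)
  bg <- planted_genes(sim, "background")
  pm <- as.matrix(pop[match(bg, pop$gene_id), -1])
  expect_true(all(abs(pm - pm[, 1]) < 1e-12))
})

test_that("replicate noise hits the calibrated correlation regime", {
  rs <- vapply(1:3, function(s) {
    sim <- simulate_dataset(sim_config(n_genes = 3000, seed = s))
    qc <- replicate_correlation(drop_spike_ins(sim$expression), sim$metadata)
    mean(qc$pairs$r)
  }, numeric(1))
  expect_true(all(rs > 0.96 & rs < 0.995))
})

test_that("contamination panel is silent without leakage and recorded with it", {
  panel <- default_contamination_panel()
  base_args <- list(n_genes = 400, seed = 1, class_markers = NULL,
                    region_genes = NULL, modules = NULL)
  clean <- simulate_dataset(do.call(sim_config, base_args))
  pm <- as.matrix(clean$expression[match(panel, clean$expression$gene_id), -1])
  expect_true(all(pm == 0))
  dirty <- simulate_dataset(do.call(sim_config, c(base_args, list(
    contamination = list(genes = panel, leakage = 0.3, n_samples = 5,
                         source_fpkm = 100)))))
  expect_length(dirty$manifest$contaminated_samples, 5)
  flags <- contamination_check(dirty$expression, panel, threshold = 10)
  expect_setequal(flags$sample_id[flags$flagged],
                  dirty$manifest$contaminated_samples)
  # everything except the panel block is untouched by planting contamination
  keep <- !clean$expression$gene_id %in% panel
  expect_identical(clean$expression[keep, ], dirty$expression[keep, ])
})

test_that("spike-ins share one ladder across samples up to noise", {
  cfg <- sim_config(n_genes = 400, seed = 2, class_markers = NULL,
                    region_genes = NULL, modules = NULL,
                    spike_ins = list(n = 20, log10_min = -1, log10_max = 3,
                                     cv = 0))
  sim <- simulate_dataset(cfg)
  spikes <- as.matrix(sim$expression[grepl("^ERCC-", sim$expression$gene_id), -1])
  expect_equal(nrow(spikes), 20)
  expect_true(all(spikes == spikes[, 1]))
})

test_that("infeasible or invalid configs are rejected", {
  expect_error(sim_config(n_genes = 100), "exceed")
  expect_error(marker_cfg(fold = 1), "folds must be > 1")
  expect_error(sim_config(n_genes = 300,
                          contamination = list(genes = "Gad1", leakage = 1.2,
                                               n_samples = 1)),
               "leakage")
})

test_that("planted overlap scenarios have the exact requested intersection", {
  # no sharing: pairwise intersections all empty
  ps <- plant_overlap_scenario(100, c(20, 30, 25), n_shared = 0, seed = 4)
  enr <- ps$scenario$enriched$dorsal
  expect_equal(length(intersect(enr$GC, enr$CA3)), 0)
  expect_equal(length(intersect(enr$GC, enr$CA1)), 0)
  # full sharing: intersection equals every list
  ps2 <- plant_overlap_scenario(50, 10, n_shared = 10, seed = 4)
  enr2 <- ps2$scenario$enriched$dorsal
  expect_setequal(Reduce(intersect, enr2), enr2$GC)
  # the planted count flows through overlap_counts
  ps3 <- plant_overlap_scenario(100, c(20, 30, 25), n_shared = 7, seed = 4)
  expect_equal(overlap_counts(ps3$scenario, pole = "dorsal"), 7)
  # inconsistent counts rejected
  expect_error(plant_overlap_scenario(100, c(20, 30, 25), n_shared = 21),
               "n_shared")
  expect_error(plant_overlap_scenario(10, 20, 5), "universe")
})
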