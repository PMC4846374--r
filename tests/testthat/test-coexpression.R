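test_that("variable-gene selection ranks by log-scale variance with an FPKM floor", {
  pop <- tibble::tibble(gene_id = c("flat", "wide", "mild", "low"),
                        A = c(20, 10, 20, 1), B = c(20, 100, 22, 40),
                        C = c(20, 50, 21, 2))
  vg <- variable_genes(pop, n = 2, fpkm_min = 5)
  expect_identical(vg, c("wide", "mild"))  # "low" fails the min filter
  expect_error(variable_genes(pop, n = 4, fpkm_min = 5), "only 3 genes")
  # brute-force sort oracle on a synthetic fixture
  sim <- simulate_dataset(module_cfg(seed = 9, n_genes = 800))
  pm <- aggregate_replicates(sim$expression, sim$metadata)
  m <- as.matrix(pm[, -1])
  keep <- apply(m, 1, min) >= 5
  v <- apply(log10(m[keep, ] + 1), 1, var)
  ids <- pm$gene_id[keep]
  oracle <- ids[order(-v, ids)][1:100]
  expect_identical(variable_genes(pm, n = 100, fpkm_min = 5), oracle)
})

test_that("dissimilarity is the affine map of Pearson correlation", {
  pop <- tibble::tibble(gene_id = c("up", "up2", "down", "flat"),
                        A = c(1, 2, 9, 5), B = c(2, 4, 7, 5),
                        C = c(3, 6, 5, 5), D = c(4, 8, 3, 5))
  expect_warning(cd <- correlation_dissimilarity(pop), "flat")
  expect_equal(cd$dropped, "flat")
  expect_equal(cd$C["up", "up2"], 1)
  expect_equal(cd$D["up", "up2"], 0)
  expect_equal(cd$C["up", "down"], -1)
  expect_equal(cd$D["up", "down"], 1)
  # D = 0.5 - C/2 elementwise
  expect_equal(cd$D, 0.5 - cd$C / 2)
})

test_that("an uncorrelated planted pair has dissimilarity centred on 0.5", {
  # independent lognormal pairs across 8 populations: D averages 0.5
  set.seed(99)
  n_pairs <- 60
  d <- vapply(seq_len(n_pairs), function(i) {
    pop <- dplyr::bind_cols(
      tibble::tibble(gene_id = c("a", "b")),
      tibble::as_tibble(matrix(stats::rlnorm(16), 2, 8,
                               dimnames = list(NULL, paste0("P", 1:8)))))
    correlation_dissimilarity(pop)$D["a", "b"]
  }, numeric(1))
  expect_lt(abs(mean(d) - 0.5), 3 * stats::sd(d) / sqrt(n_pairs))
})

test_that("DIANA reproduces the hand-executed trace on the 4-object toy", {
  D <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.1
  D["c", "d"] <- D["d", "c"] <- 0.1
  diag(D) <- 0
  tree <- diana_cluster(D)
  # hand trace: first split {a,b} | {c,d} at diameter 0.9, then both pairs
  # split at 0.1
  expect_equal(sort(tree$height), c(0.1, 0.1, 0.9))
  expect_equal(unname(cutree(tree, 2)), c(1, 1, 2, 2))
  expect_equal(unname(cutree(tree, 4)), 1:4)
  expect_error(diana_cluster(matrix(0, 1, 1)), "at least 2")
})

test_that("DIANA splits two well-separated blocks first", {
  set.seed(17)
  n <- 12
  D <- matrix(stats::runif(n * n, 0.85, 0.95), n, n)
  D[1:6, 1:6] <- stats::runif(36, 0, 0.1)
  D[7:12, 7:12] <- stats::runif(36, 0, 0.1)
  D <- (D + t(D)) / 2; diag(D) <- 0
  dimnames(D) <- list(paste0("g", 1:n), paste0("g", 1:n))
  tree <- diana_cluster(D)
  expect_equal(unname(cutree(tree, 2)), rep(1:2, each = 6))
  # heights never increase from root to leaves
  expect_true(all(diff(tree$height) >= 0))  # hclust encoding: sorted heights
})

test_that("DIANA agrees with the reference implementation on random matrices", {
  skip_if_not_installed("cluster")
  set.seed(23)
  for (n in c(8, 15)) {
    pts <- matrix(stats::rnorm(n * 3), n, 3)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("g", 1:n), paste0("g", 1:n))
    mine <- diana_cluster(D)
    ref <- stats::as.hclust(cluster::diana(as.dist(D), diss = TRUE))
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-10)
    for (k in c(2, 3, 4)) {
      expect_equal(partition_agreement(cutree(mine, k)[paste0("g", 1:n)],
                                       cutree(ref, k)[paste0("g", 1:n)]), 1)
    }
  }
})

test_that("module cutting spans singletons to one module and recovers counts", {
  D <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.1
  D["c", "d"] <- D["d", "c"] <- 0.1
  diag(D) <- 0
  tree <- diana_cluster(D)
  expect_equal(cut_modules(tree, height = 0)$k, 4)
  expect_equal(cut_modules(tree, height = 2)$k, 1)
  expect_equal(cut_modules(tree, k = 2)$k, 2)
})

test_that("planted modules are recovered at the planted count", {
  sim <- simulate_dataset(module_cfg(seed = 3, n_genes = 1200))
  pm <- aggregate_replicates(sim$expression, sim$metadata)
  vg <- variable_genes(pm, n = 320, fpkm_min = 5)
  cd <- correlation_dissimilarity(pm, vg)
  tree <- diana_cluster(cd$D)
  mods <- cut_modules(tree, k = 8, pop = pm)
  truth <- sim$manifest$genes$module[match(mods$assignment$gene_id,
                                           sim$manifest$genes$gene_id)]
  expect_gte(partition_agreement(mods$assignment$module, truth), 0.9)
  expect_equal(mods$k, 8)
  # module profiles: one value per population, each gene max-normalized
  expect_equal(names(mods$profiles),
               c("module", colnames(as.matrix(pm[, -1]))))
  expect_true(all(as.matrix(mods$profiles[, -1]) <= 1 + 1e-12))
})

test_that("hypergeometric set test matches enumeration and edge cases", {
  universe <- sprintf("u%02d", 1:12)
  mod <- universe[1:4]
  # module identical to the set: p = 1 / choose(12, 4)
  res <- gene_set_test(mod, list(hit = mod), universe)
  expect_equal(res$p_value, 1 / choose(12, 4))
  # disjoint set of size 8: overlap 0 is the guaranteed minimum... here the
  # minimum possible overlap is 0, so p = 1
  res2 <- gene_set_test(mod, list(none = universe[5:8]), universe)
  expect_equal(res2$p_value, 1)
  # enumeration oracle: P(overlap >= k) by enumerating all C(12,4) modules
  set <- universe[c(1, 3, 5, 7, 9)]
  subs <- utils::combn(12, 4)
  ov_all <- apply(subs, 2, function(s) length(intersect(universe[s], set)))
  for (k in 0:4) {
    expect_equal(
      gene_set_test(universe[subs[, which(ov_all == k)[1]]],
                    list(s = set), universe)$p_value,
      mean(ov_all >= k))
  }
  expect_error(gene_set_test(mod, list(a = mod), character()), "empty")
  expect_error(gene_set_test(c(mod, "zz"), list(a = mod), universe), "outside")
})

test_that("GMT parsing returns named gene sets", {
  tf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), tf)
  gs <- read_gmt(tf)
  expect_equal(names(gs), c("setA", "setB"))
  expect_equal(gs$setA, c("g1", "g2", "g3"))
})
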