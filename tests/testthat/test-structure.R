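test_that("profile transform normalizes log10(FPKM + 1) by the sample sum", {
  p <- transform_profiles(tibble::tibble(gene_id = c("a", "b"), s = c(9, 99)))
  expect_equal(p$s, c(1 / 3, 2 / 3))
  p2 <- transform_profiles(tibble::tibble(gene_id = c("a", "b", "c"),
                                          s = c(0, 0, 9)))
  expect_equal(p2$s, c(0, 0, 1))
  expect_error(transform_profiles(tibble::tibble(gene_id = "a", bad = 0)),
               "bad")
  # random fixture: profiles sum to 1 and match a two-pass recomputation
  set.seed(21)
  x <- tibble::tibble(gene_id = paste0("g", 1:50),
                      s1 = stats::rexp(50, 0.1), s2 = stats::rexp(50, 0.01))
  pr <- transform_profiles(x)
  expect_equal(sum(pr$s1), 1)
  expect_equal(sum(pr$s2), 1)
  l <- log10(x$s2 + 1)
  expect_equal(pr$s2, l / sum(l))
})

test_that("Jensen-Shannon distance matches hand-expanded values and bounds", {
  expect_equal(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  # hand expansion: JSD((1,0),(1/2,1/2)) = log2(4/3)/2 + ... = 0.311278
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)), 0.311278, tolerance = 1e-6)
  expect_equal(js_distance(c(1, 0), c(0.5, 0.5)), 0.557923, tolerance = 1e-6)
  expect_error(js_distance(c(1, 0), c(1, 0, 0)), "length")
})

test_that("the pairwise distance matrix is symmetric with zero diagonal", {
  set.seed(5)
  x <- tibble::tibble(gene_id = paste0("g", 1:100),
                      a = stats::rexp(100), b = stats::rexp(100),
                      c = stats::rexp(100))
  d <- js_distance_matrix(transform_profiles(x))
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("complete linkage produces the forced topology and exact ultrametrics", {
  d <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- agglomerative_dendrogram(d)
  expect_equal(tree$height, c(0.1, 0.9))
  expect_equal(sort(tree$labels[-tree$merge[1, ]]), c("A", "B"))
  # ultrametric input: merge heights reproduce the ultrametric exactly
  u <- matrix(0.8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  u["a", "b"] <- u["b", "a"] <- 0.2
  u["a", "c"] <- u["c", "a"] <- u["b", "c"] <- u["c", "b"] <- 0.5
  diag(u) <- 0
  tu <- agglomerative_dendrogram(u)
  expect_equal(tu$height, c(0.2, 0.5, 0.8))
  coph <- as.matrix(stats::cophenetic(tu))[rownames(u), colnames(u)]
  expect_equal(coph, u)
  expect_error(agglomerative_dendrogram(matrix(0, 1, 1)), "at least 2")
})

test_that("dendrogram heights are monotone under complete linkage", {
  set.seed(31)
  pts <- matrix(stats::rnorm(20), 10, 2)
  tree <- agglomerative_dendrogram(as.matrix(dist(pts)))
  expect_true(all(diff(tree$height) >= 0))
})

test_that("classical MDS embeds exact configurations exactly", {
  # equilateral triangle, side 1
  d3 <- matrix(1, 3, 3, dimnames = list(1:3, 1:3)); diag(d3) <- 0
  fit <- classical_mds(d3, k = 2)
  emb <- as.matrix(fit$points[, -1])
  expect_equal(as.vector(dist(emb)), rep(1, 3), tolerance = 1e-9)
  # collinear points at 0, 1, 3: exact with a null second axis
  d1 <- as.matrix(dist(c(0, 1, 3)))
  fit1 <- classical_mds(d1, k = 2)
  emb1 <- as.matrix(fit1$points[, -1])
  expect_equal(as.vector(dist(emb1)), as.vector(dist(c(0, 1, 3))),
               tolerance = 1e-9)
  expect_lt(max(abs(emb1[, 2])), 1e-6)
  expect_error(classical_mds(d3, k = 3), "smaller")
})

test_that("MDS sign convention makes output deterministic", {
  set.seed(41)
  pts <- matrix(stats::rnorm(16), 8, 2)
  d <- as.matrix(dist(pts))
  f1 <- classical_mds(d)
  f2 <- classical_mds(d)
  expect_identical(f1$points, f2$points)
  expect_gte(f1$points$dim1[1], 0)
})

test_that("heat-map normalization divides each gene by its max", {
  x <- tibble::tibble(gene_id = c("a", "z"), s1 = c(10, 0), s2 = c(5, 0),
                      s3 = c(20, 0))
  n <- heatmap_normalize(x)
  expect_equal(unlist(n[1, -1], use.names = FALSE), c(0.5, 0.25, 1.0))
  expect_equal(unlist(n[2, -1], use.names = FALSE), c(0, 0, 0))
  set.seed(3)
  r <- tibble::tibble(gene_id = paste0("g", 1:30),
                      a = stats::rexp(30), b = stats::rexp(30))
  rn <- as.matrix(heatmap_normalize(r)[, -1])
  expect_equal(unname(apply(rn, 1, max)), rep(1, 30))
})

test_that("newick export round-trips through ape", {
  d <- as.matrix(dist(c(0, 1, 3, 7)))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tree <- agglomerative_dendrogram(d)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, tf)
  phy <- ape::read.tree(tf)
  expect_setequal(phy$tip.label, letters[1:4])
})
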