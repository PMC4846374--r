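#' Transform FPKM columns into probability profiles
#'
#' Each sample (or population) column is converted to a probability
#' distribution over genes: add a pseudocount of 1, take log10, and divide by
#' the column sum of the transformed values. These profiles feed the
#' Jensen-Shannon distance.
#'
#' @param x Tibble with `gene_id` plus numeric columns (replicate-level or
#'   population-averaged FPKM).
#' @return Tibble of the same shape whose numeric columns are non-negative
#'   and sum to 1.
#' @export
#' @examples
#' transform_profiles(tibble::tibble(gene_id = c("a", "b"), s = c(9, 99)))
transform_profiles <- function(x) {
  m <- as_fpkm_matrix(x)
  if (any(m < 0)) abort("FPKM values must be non-negative")
  l <- log10(m + 1)
  sums <- colSums(l)
  zero <- colnames(l)[sums == 0]
  if (length(zero)) {
    abort(paste0("all-zero sample(s), profile undefined: ", fmt_ids(zero)))
  }
  fpkm_tibble(sweep(l, 2, sums, `/`))
}

#' Jensen-Shannon divergence and distance
#'
#' The divergence is the mean of the two Kullback-Leibler divergences to the
#' midpoint distribution, with base-2 logarithms and the convention
#' `0 * log(0) = 0`; the distance is its square root, a metric bounded by
#' `[0, 1]`.
#'
#' @param p,q Non-negative numeric vectors of equal length summing to 1.
#' @return A single number.
#' @export
#' @examples
#' js_distance(c(1, 0), c(0.5, 0.5))
js_divergence <- function(p, q) {
  if (length(p) != length(q)) abort("profiles differ in length")
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  (kl(p) + kl(q)) / 2
}

#' @rdname js_divergence
#' @export
js_distance <- function(p, q) sqrt(js_divergence(p, q))

#' Pairwise Jensen-Shannon distance matrix
#'
#' @param profiles Probability-profile tibble from [transform_profiles()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = column
#'   names.
#' @export
js_distance_matrix <- function(profiles) {
  m <- as_fpkm_matrix(profiles)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- js_distance(m[, i], m[, j])
    }
  }
  d
}

#' Complete-linkage agglomerative dendrogram
#'
#' Agglomerative clustering of a distance matrix with complete linkage: each
#' merge height is the maximum pairwise distance between the merged groups,
#' so heights are monotone non-decreasing along merges.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param method Linkage passed to [stats::hclust()] (complete by default).
#' @return An `hclust` object.
#' @export
agglomerative_dendrogram <- function(d, method = "complete") {
  dd <- as.dist(d)
  if (attr(dd, "Size") < 2) abort("need at least 2 items to cluster")
  hclust(dd, method = method)
}

#' Export a dendrogram as Newick text
#'
#' @param tree An `hclust` (or `phylo`) object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- if (inherits(tree, "phylo")) tree else ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, takes the top-k non-negative
#' eigenpairs, and scales eigenvectors by the square roots of their
#' eigenvalues. Output is unique up to rotation/reflection; for
#' reproducibility each axis is flipped so its first nonzero loading is
#' positive.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param k Embedding dimension (default 2; must be < number of items).
#' @return Object of class `mds_result`: list with `points` (tibble: `sample`
#'   plus `dim1..dimk`) and `eig` (all eigenvalues).
#' @export
classical_mds <- function(d, k = 2) {
  dd <- as.dist(d)
  n <- attr(dd, "Size")
  if (k >= n) abort(sprintf("k (%d) must be smaller than the number of items (%d)", k, n))
  fit <- cmdscale(dd, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  structure(list(points = bind_cols(tibble(sample = rownames(pts)),
                                    as_tibble(pts)),
                 eig = fit$eig),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("classical MDS,", nrow(x$points), "items,",
      ncol(x$points) - 1, "dimensions\n")
  print(x$points, ...)
  invisible(x)
}

#' Per-gene max normalization for heat maps
#'
#' Divides each gene's values by its maximum across samples, so every row
#' peaks at 1; all-zero genes are left at zero.
#'
#' @param x Tibble with `gene_id` plus numeric columns.
#' @return Tibble of the same shape with values in `[0, 1]`.
#' @export
heatmap_normalize <- function(x) {
  m <- as_fpkm_matrix(x)
  mx <- row_max(m)
  mx[mx == 0] <- 1
  fpkm_tibble(m / mx)
}
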