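#' Divisive (DIANA) hierarchical clustering
#'
#' Divisive analysis clustering of a dissimilarity matrix: starting from one
#' all-inclusive cluster, the cluster with the largest diameter (maximum
#' pairwise dissimilarity) is repeatedly split. A split seeds a splinter
#' group with the object of maximal average dissimilarity to the rest, then
#' iteratively moves over the object whose average dissimilarity to the
#' remainder most exceeds its average dissimilarity to the splinter, until no
#' object prefers the splinter. The height of each split is the diameter of
#' the cluster being split, so heights decrease from root to leaves. Ties are
#' broken by lowest index, making the tree fully deterministic.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal (row/column
#'   names become leaf labels).
#' @return An object of class `c("diana_tree", "hclust")` with the usual
#'   `merge`, `height`, `order`, `labels` fields, so [stats::cutree()] and
#'   `as.dendrogram()` apply.
#' @seealso [cut_modules()]
#' @export
diana_cluster <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) abort("need at least 2 objects to cluster")
  if (!isTRUE(all.equal(D, t(D)))) abort("dissimilarity matrix must be symmetric")
  labels <- rownames(D) %||% as.character(seq_len(n))

  # Recursive splitting; returns a node list (leaf index or children+height).
  split_cluster <- function(idx) {
    if (length(idx) == 1) return(list(leaf = idx))
    sub <- D[idx, idx, drop = FALSE]
    diam <- max(sub)
    if (length(idx) == 2) {
      return(list(height = diam,
                  left = list(leaf = idx[1]), right = list(leaf = idx[2])))
    }
    # seed the splinter group with the object of max average dissimilarity
    avg <- rowSums(sub) / (length(idx) - 1)
    seed <- which.max(avg)           # which.max takes the lowest index on ties
    in_splinter <- rep(FALSE, length(idx))
    in_splinter[seed] <- TRUE
    repeat {
      A <- which(!in_splinter)
      B <- which(in_splinter)
      if (length(A) == 1) break
      a_avg <- rowSums(sub[A, A, drop = FALSE]) / (length(A) - 1)
      b_avg <- rowMeans(sub[A, B, drop = FALSE])
      diff <- a_avg - b_avg
      best <- which.max(diff)
      if (diff[best] <= 0) break
      in_splinter[A[best]] <- TRUE
    }
    list(height = diam,
         left = split_cluster(idx[!in_splinter]),
         right = split_cluster(idx[in_splinter]))
  }
  root <- split_cluster(seq_len(n))

  # Flatten to hclust encoding: collect internal nodes post-order (children
  # first), then stable-sort by height so merge heights are non-decreasing
  # while children still precede parents.
  nodes <- list()
  walk <- function(node) {
    if (!is.null(node$leaf)) return(-node$leaf)
    l <- walk(node$left)
    r <- walk(node$right)
    nodes[[length(nodes) + 1]] <<- list(l = l, r = r, h = node$height)
    length(nodes)
  }
  walk(root)
  hs <- vapply(nodes, `[[`, numeric(1), "h")
  ord <- order(hs)                    # stable: equal heights keep post-order
  remap <- integer(length(nodes))
  remap[ord] <- seq_along(nodes)
  merge <- matrix(0L, length(nodes), 2)
  for (i in seq_along(nodes)) {
    nd <- nodes[[ord[i]]]
    merge[i, 1] <- if (nd$l < 0) nd$l else remap[nd$l]
    merge[i, 2] <- if (nd$r < 0) nd$r else remap[nd$r]
  }
  leaf_order <- function(node) {
    if (!is.null(node$leaf)) return(node$leaf)
    c(leaf_order(node$left), leaf_order(node$right))
  }
  structure(list(merge = merge, height = hs[ord], order = leaf_order(root),
                 labels = labels, method = "diana",
                 call = match.call(), dist.method = "user"),
            class = c("diana_tree", "hclust"))
}
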