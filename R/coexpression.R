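#' Most variable genes across populations
#'
#' Filters to genes whose minimum population-mean FPKM meets `fpkm_min`
#' (reading the minimum-expression cutoff as min-across-populations; a
#' max-based reading is selectable), ranks by variance of `log10(FPKM + 1)`
#' across populations, and keeps the top `n`. Variance on the log scale
#' prevents a handful of very high expressors from dominating the ranking; a
#' raw-scale option exists.
#'
#' @param pop Population-mean tibble.
#' @param n Number of genes to keep (default 1000).
#' @param fpkm_min Expression floor (default 5).
#' @param scale `"log10"` (default) or `"raw"` variance.
#' @param filter `"min"` (default) or `"max"`: which across-population
#'   summary must reach `fpkm_min`.
#' @return Character vector of `n` gene ids, most variable first; ties broken
#'   by gene id.
#' @export
variable_genes <- function(pop, n = 1000, fpkm_min = 5,
                           scale = c("log10", "raw"),
                           filter = c("min", "max")) {
  scale <- match.arg(scale)
  filter <- match.arg(filter)
  m <- as_fpkm_matrix(pop)
  keep <- if (filter == "min") row_min(m) >= fpkm_min else row_max(m) >= fpkm_min
  if (sum(keep) < n) {
    abort(sprintf("only %d genes pass FPKM_min >= %g but n = %d requested",
                  sum(keep), fpkm_min, n))
  }
  m <- m[keep, , drop = FALSE]
  v <- if (scale == "log10") {
    apply(log10(m + 1), 1, var)
  } else {
    apply(m, 1, var)
  }
  ids <- rownames(m)
  ids[order(-v, ids)][seq_len(n)]
}

#' Gene-gene correlation and dissimilarity matrices
#'
#' Pearson correlation of each gene pair across datasets (population means by
#' default) gives `C`; the dissimilarity is the affine map
#' `D = 1 - (C + 1) / 2`, sending perfect correlation to 0 and perfect
#' anti-correlation to 1. Genes with zero variance across datasets have no
#' defined correlation and are dropped with a warning.
#'
#' @param pop Population-mean (or replicate-level) tibble.
#' @param genes Genes to include (default: all rows).
#' @return Object of class `cor_dissim`: list with matrices `C` and `D` and
#'   the vector `dropped` of zero-variance genes.
#' @export
correlation_dissimilarity <- function(pop, genes = NULL) {
  m <- as_fpkm_matrix(pop)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) abort(paste0("genes absent from matrix: ", fmt_ids(miss)))
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2) abort("need at least 2 datasets to correlate genes")
  v <- apply(m, 1, var)
  dropped <- rownames(m)[v == 0]
  if (length(dropped)) {
    warn(paste0("dropping zero-variance gene(s): ", fmt_ids(dropped)))
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("fewer than 2 genes with nonzero variance")
  C <- cor(t(m))
  if (any(!is.finite(C))) abort("undefined correlation for a retained gene")
  D <- 1 - (C + 1) / 2
  structure(list(C = C, D = D, dropped = dropped), class = "cor_dissim")
}

#' Cut a divisive tree into co-expression modules
#'
#' Connected subtrees below the cut become modules. Because absolute cut
#' heights are not transferable between divisive-tree height conventions,
#' the default cuts to a requested number of modules (`k`); an
#' absolute-height mode (`height`) is available for calibrated pipelines.
#' Module labels (`M1`, `M2`, ...) are ordered by first member appearance.
#'
#' @param tree A `diana_tree` (or any `hclust`) over genes.
#' @param k Number of modules (default 8; ignored when `height` given).
#' @param height Absolute cut height; a cut above the root yields one module.
#' @param pop Optional population-mean tibble; if given, per-module mean
#'   profiles of max-normalized expression are computed.
#' @return Object of class `module_set`: `assignment` tibble (`gene_id`,
#'   `module`), `profiles` tibble or `NULL`, and the cut used.
#' @export
cut_modules <- function(tree, k = 8, height = NULL, pop = NULL) {
  stopifnot(inherits(tree, "hclust"))
  if (!is.null(height)) {
    if (height < 0) abort("cut height must be >= 0")
    grp <- if (height >= max(tree$height)) {
      setNames(rep(1L, length(tree$labels)), tree$labels)
    } else {
      cutree(tree, h = height)
    }
  } else {
    k <- min(k, length(tree$labels))
    grp <- cutree(tree, k = k)
  }
  lab <- paste0("M", match(grp, unique(grp)))
  assignment <- tibble(gene_id = names(grp), module = lab)
  profiles <- NULL
  if (!is.null(pop)) {
    profiles <- module_profiles(assignment, pop)
  }
  structure(list(assignment = assignment, profiles = profiles,
                 k = length(unique(lab)), height = height),
            class = "module_set")
}

#' Per-module mean expression profiles
#'
#' Each member gene is max-normalized across populations
#' ([heatmap_normalize()]) and the module profile is the per-population mean
#' over members.
#'
#' @param assignment Tibble with `gene_id` and `module`.
#' @param pop Population-mean tibble containing those genes.
#' @return Tibble: `module`, then one column per population.
#' @export
module_profiles <- function(assignment, pop) {
  norm <- heatmap_normalize(pop)
  m <- as_fpkm_matrix(norm)
  miss <- setdiff(assignment$gene_id, rownames(m))
  if (length(miss)) abort(paste0("module genes absent from matrix: ", fmt_ids(miss)))
  mods <- unique(assignment$module)
  prof <- t(vapply(mods, function(md) {
    colMeans(m[assignment$gene_id[assignment$module == md], , drop = FALSE])
  }, numeric(ncol(m))))
  bind_cols(tibble(module = mods), as_tibble(prof))
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- table(x$assignment$module)
  cat(x$k, "modules over", nrow(x$assignment), "genes\n")
  print(sizes)
  invisible(x)
}

#' Hypergeometric gene-set enrichment test
#'
#' One-sided (upper-tail) hypergeometric test of each annotation set against
#' a gene module within a common universe, with Benjamini-Hochberg
#' adjustment across sets. A lightweight stand-in for web-service annotation
#' tools.
#'
#' @param module Character vector of module gene ids (subset of `universe`).
#' @param sets Named list of annotation gene sets (intersected with the
#'   universe).
#' @param universe Character vector of all eligible gene ids.
#' @return Tibble: `set`, `overlap`, `set_size`, `module_size`, `p_value`,
#'   `p_adjust`, sorted by `p_value`.
#' @export
gene_set_test <- function(module, sets, universe) {
  if (length(universe) == 0) abort("universe is empty")
  out <- setdiff(module, universe)
  if (length(out)) abort(paste0("module genes outside the universe: ", fmt_ids(out)))
  N <- length(unique(universe))
  nmod <- length(unique(module))
  res <- lapply(names(sets), function(sn) {
    s <- intersect(unique(sets[[sn]]), universe)
    ov <- length(intersect(module, s))
    p <- phyper(ov - 1, length(s), N - length(s), nmod, lower.tail = FALSE)
    tibble(set = sn, overlap = ov, set_size = length(s),
           module_size = nmod, p_value = p)
  }) |> bind_rows()
  res$p_adjust <- p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value, .data$set)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated -- name, description,
#' then member gene ids.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}
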