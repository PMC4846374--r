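#' Expressed-gene filter
#'
#' A gene is expressed if its population-mean FPKM strictly exceeds the
#' threshold in at least one population (default FPKM > 10).
#'
#' @param pop Population-mean tibble from [aggregate_replicates()].
#' @param threshold FPKM cutoff (strict `>`).
#' @param populations Optional subset of population columns to scan.
#' @return Character vector of expressed gene ids, in matrix order.
#' @export
expressed_genes <- function(pop, threshold = 10, populations = NULL) {
  m <- as_fpkm_matrix(pop)
  if (!is.null(populations)) {
    miss <- setdiff(populations, colnames(m))
    if (length(miss)) abort(paste0("unknown population(s): ", fmt_ids(miss)))
    m <- m[, populations, drop = FALSE]
  }
  rownames(m)[row_max(m) > threshold]
}

check_target <- function(pops, target) {
  if (length(target) == 0) abort("target population set is empty")
  miss <- setdiff(target, pops)
  if (length(miss)) abort(paste0("unknown target population(s): ", fmt_ids(miss)))
  if (length(setdiff(pops, target)) == 0) {
    abort("target must be a proper subset of the populations")
  }
}

#' Mean-FPKM fold-enrichment marker calling
#'
#' A gene is called X-fold enriched in the target population(s) when it is
#' expressed and its mean FPKM in every target population is at least X times
#' its mean FPKM in every other population, i.e.
#' `min(target means) >= X * max(off-target means)`. This is the rule used
#' for cell-class marker lists (X = 3 by convention).
#'
#' @param pop Population-mean tibble.
#' @param target Character vector of target population column names (a proper
#'   nonempty subset).
#' @param fold Enrichment factor X (> 1).
#' @param strict If `TRUE` require a strictly greater ratio; default closed
#'   (`>=`), since "at least X-fold" is the operative definition.
#' @param expressed_threshold FPKM cutoff for the expressed filter (applied
#'   over all populations in `pop`); `NULL` disables it.
#' @return Tibble of marker calls: `gene_id`, `rule`, `target`, `fold`
#'   (achieved min ratio; `Inf` when off-target means are all zero),
#'   `target_mean_fpkm`; sorted by decreasing fold (`Inf` first).
#' @export
mean_fold_markers <- function(pop, target, fold = 3, strict = FALSE,
                              expressed_threshold = 10) {
  if (fold <= 1) abort("fold must be > 1")
  m <- as_fpkm_matrix(pop)
  check_target(colnames(m), target)
  off <- setdiff(colnames(m), target)
  tmin <- row_min(m[, target, drop = FALSE])
  omax <- row_max(m[, off, drop = FALSE])
  called <- if (strict) tmin > fold * omax else tmin >= fold * omax
  called <- called & tmin > 0
  if (!is.null(expressed_threshold)) {
    called <- called & rownames(m) %in% expressed_genes(pop, expressed_threshold)
  }
  ratio <- ifelse(omax == 0, Inf, tmin / omax)
  tmean <- rowMeans(m[, target, drop = FALSE])
  tibble(gene_id = rownames(m)[called],
         rule = "mean_fold",
         target = paste(target, collapse = "+"),
         fold = unname(ratio[called]),
         target_mean_fpkm = unname(tmean[called])) |>
    arrange(desc(.data$fold), .data$gene_id)
}

#' Per-replicate fold-enrichment marker calling
#'
#' The stricter replicate-level rule used for dendrogram-branch markers: a
#' gene is called when it is expressed and every replicate of the target
#' population(s) is at least `fold` times every individual non-target
#' replicate (`compare = "each"`). A milder variant compares each target
#' replicate against the mean of the non-target replicates
#' (`compare = "mean"`).
#'
#' @param expr Replicate-level expression tibble.
#' @param meta Sample metadata.
#' @param target Target population labels (proper nonempty subset).
#' @param fold Enrichment factor (default 2).
#' @param compare `"each"` (every non-target replicate) or `"mean"`.
#' @param expressed_threshold FPKM cutoff applied to population means;
#'   `NULL` disables.
#' @return Tibble of marker calls (same shape as [mean_fold_markers()]).
#' @export
per_replicate_markers <- function(expr, meta, target, fold = 2,
                                  compare = c("each", "mean"),
                                  expressed_threshold = 10) {
  compare <- match.arg(compare)
  validate_expression_matrix(expr)
  validate_sample_metadata(meta, expr)
  m <- as_fpkm_matrix(expr)
  labs <- population_labels(meta)
  check_target(unique(labs), target)
  t_ids <- meta$sample_id[labs %in% target]
  o_ids <- meta$sample_id[!labs %in% target]
  tmin <- row_min(m[, t_ids, drop = FALSE])
  oref <- if (compare == "each") {
    row_max(m[, o_ids, drop = FALSE])
  } else {
    rowMeans(m[, o_ids, drop = FALSE])
  }
  called <- tmin >= fold * oref & tmin > 0
  if (!is.null(expressed_threshold)) {
    pop <- aggregate_replicates(expr, meta)
    called <- called & rownames(m) %in% expressed_genes(pop, expressed_threshold)
  }
  ratio <- ifelse(oref == 0, Inf, tmin / oref)
  tmean <- rowMeans(m[, t_ids, drop = FALSE])
  tibble(gene_id = rownames(m)[called],
         rule = paste0("per_replicate_", compare),
         target = paste(target, collapse = "+"),
         fold = unname(ratio[called]),
         target_mean_fpkm = unname(tmean[called])) |>
    arrange(desc(.data$fold), .data$gene_id)
}

#' Dorsal- and ventral-enriched genes within a cell class
#'
#' Compares a cell class against itself at the opposite pole: among genes
#' expressed in at least one of the two pole populations, the dorsal list
#' holds genes whose dorsal mean is at least `fold` times the ventral mean,
#' and symmetrically for the ventral list. The two lists are disjoint by
#' construction (fold > 1).
#'
#' @param pop Population-mean tibble containing `<class>_dorsal` and
#'   `<class>_ventral` columns.
#' @param cell_class Cell class with both poles profiled (e.g. `"CA1"`).
#' @param fold Enrichment factor (default 2).
#' @param expressed_threshold FPKM cutoff defining the class's expressed
#'   universe (strict `>`, scanned over the two pole populations).
#' @param strict If `TRUE`, require a strictly greater ratio.
#' @return Tibble: `gene_id`, `pole` (`dorsal`/`ventral`), `fold` (achieved
#'   ratio, `Inf` against zero), `dorsal_mean`, `ventral_mean`. The class's
#'   expressed universe is attached as attribute `universe`.
#' @export
pole_enriched_genes <- function(pop, cell_class, fold = 2,
                                expressed_threshold = 10, strict = FALSE) {
  if (fold <= 1) abort("fold must be > 1")
  m <- as_fpkm_matrix(pop)
  d_col <- paste0(cell_class, "_dorsal")
  v_col <- paste0(cell_class, "_ventral")
  miss <- setdiff(c(d_col, v_col), colnames(m))
  if (length(miss)) {
    abort(paste0("missing pole population(s) for ", cell_class, ": ",
                 fmt_ids(miss)))
  }
  d <- m[, d_col]
  v <- m[, v_col]
  universe <- rownames(m)[pmax(d, v) > expressed_threshold]
  in_univ <- rownames(m) %in% universe
  ge <- if (strict) function(a, b) a > b else function(a, b) a >= b
  d_hit <- in_univ & ge(d, fold * v) & d > 0
  v_hit <- in_univ & ge(v, fold * d) & v > 0
  out <- bind_rows(
    tibble(gene_id = rownames(m)[d_hit], pole = "dorsal",
           fold = unname(ifelse(v[d_hit] == 0, Inf, d[d_hit] / v[d_hit])),
           dorsal_mean = unname(d[d_hit]), ventral_mean = unname(v[d_hit])),
    tibble(gene_id = rownames(m)[v_hit], pole = "ventral",
           fold = unname(ifelse(d[v_hit] == 0, Inf, v[v_hit] / d[v_hit])),
           dorsal_mean = unname(d[v_hit]), ventral_mean = unname(v[v_hit]))
  ) |>
    arrange(.data$pole, desc(.data$fold), .data$gene_id)
  attr(out, "universe") <- universe
  attr(out, "cell_class") <- cell_class
  out
}
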