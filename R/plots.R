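#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result objects.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name hippoexpr-autoplot
NULL

#' @rdname hippoexpr-autoplot
#' @export
autoplot.qc_correlation <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$population, y = .data$r)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(y = "pairwise replicate Pearson r", x = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname hippoexpr-autoplot
#' @export
autoplot.qc_report <- function(object, ...) autoplot(object$replicates, ...)

#' @rdname hippoexpr-autoplot
#' @export
autoplot.overlap_null <- function(object, ...) {
  pole_keep <- setdiff(names(object$null_draws), "combined")
  df <- bind_rows(lapply(pole_keep, function(pn) {
    tibble(pole = pn, null = object$null_draws[[pn]])
  }))
  obs <- object$results[object$results$pole %in% pole_keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "red") +
    ggplot2::facet_wrap(~pole) +
    ggplot2::labs(x = "null overlap count", y = "Monte Carlo replicates") +
    ggplot2::theme_bw()
}

#' @rdname hippoexpr-autoplot
#' @export
autoplot.mds_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               label = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_bw()
}

#' @rdname hippoexpr-autoplot
#' @export
autoplot.module_set <- function(object, ...) {
  if (is.null(object$profiles)) {
    abort("module_set has no profiles; pass `pop` to cut_modules()")
  }
  df <- tidyr::pivot_longer(object$profiles, -"module",
                            names_to = "population", values_to = "expression")
  df$population <- factor(df$population, levels = names(object$profiles)[-1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population,
                                   y = .data$expression, group = 1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = NULL, y = "mean max-normalized FPKM") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Marker heat map of max-normalized expression
#'
#' Replicate-level heat map for a set of genes, each gene max-normalized
#' across samples, the standard display for marker-gene panels.
#'
#' @param expr Expression tibble.
#' @param meta Sample metadata (orders the columns by population).
#' @param genes Genes to display (rows).
#' @return A `ggplot`.
#' @export
plot_marker_heatmap <- function(expr, meta, genes) {
  miss <- setdiff(genes, expr$gene_id)
  if (length(miss)) abort(paste0("genes absent from matrix: ", fmt_ids(miss)))
  norm <- heatmap_normalize(expr[match(genes, expr$gene_id), , drop = FALSE])
  df <- tidyr::pivot_longer(norm, -"gene_id", names_to = "sample_id",
                            values_to = "value")
  df$sample_id <- factor(df$sample_id, levels = meta$sample_id)
  df$gene_id <- factor(df$gene_id, levels = rev(genes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "norm. FPKM") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
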