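#' Within-population replicate correlations
#'
#' Pairwise Pearson correlation of whole-transcriptome FPKM vectors between
#' replicates of the same population. A population passes only if every pair
#' exceeds the threshold (all-pairs, the strictest reading of a per-class
#' reproducibility gate); a zero-variance replicate vector makes the
#' correlation undefined and is treated as a failure.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param meta Sample metadata.
#' @param genes Optional gene ids to restrict to (e.g. the spike-in block).
#' @param log_scale If `TRUE`, correlate `log10(FPKM + 1)` instead of raw
#'   FPKM. Defaults to raw, the scale on which replicate scatter is usually
#'   reported.
#' @param threshold Minimum pairwise r for a pass (0.90 by default, the
#'   conventional replicate-reproducibility gate).
#' @return Object of class `qc_correlation`: list with `pairs` (tibble:
#'   population, sample_1, sample_2, r), `populations` (tibble: population,
#'   min_r, mean_r, pass), and the threshold used.
#' @export
replicate_correlation <- function(expr, meta, genes = NULL, log_scale = FALSE,
                                  threshold = 0.90) {
  validate_expression_matrix(expr)
  validate_sample_metadata(meta, expr)
  m <- as_fpkm_matrix(expr)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss) == length(genes)) abort("none of the requested genes are present")
    m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  }
  if (log_scale) m <- log10(m + 1)
  labs <- population_labels(meta)
  pairs <- list()
  for (p in unique(labs)) {
    ids <- meta$sample_id[labs == p]
    if (length(ids) < 2) abort(paste0("population '", p, "' has < 2 replicates"))
    cmb <- utils::combn(ids, 2)
    r <- apply(cmb, 2, function(pr) {
      x <- m[, pr[1]]; y <- m[, pr[2]]
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      cor(x, y)
    })
    pairs[[p]] <- tibble(population = p, sample_1 = cmb[1, ],
                         sample_2 = cmb[2, ], r = r)
  }
  pairs <- bind_rows(pairs)
  pops <- pairs |>
    group_by(.data$population) |>
    summarise(min_r = suppressWarnings(min(.data$r, na.rm = FALSE)),
              mean_r = mean(.data$r),
              pass = all(!is.na(.data$r)) && all(.data$r > threshold),
              .groups = "drop")
  structure(list(pairs = pairs, populations = pops, threshold = threshold,
                 log_scale = log_scale),
            class = "qc_correlation")
}

#' Spike-in reproducibility check
#'
#' [replicate_correlation()] restricted to the ERCC-like spike-in block; the
#' spike-ins share one concentration ladder, so cross-replicate correlation
#' reflects quantification fidelity rather than biology.
#'
#' @inheritParams replicate_correlation
#' @param pattern Regular expression identifying spike-in gene ids.
#' @return A `qc_correlation` object over the spike-in block.
#' @export
spike_in_correlation <- function(expr, meta, pattern = "^ERCC-",
                                 threshold = 0.90) {
  spikes <- expr$gene_id[grepl(pattern, expr$gene_id)]
  if (!length(spikes)) abort("no spike-in genes match the pattern")
  replicate_correlation(expr, meta, genes = spikes, threshold = threshold)
}

#' Contamination-panel purity check
#'
#' Flags samples in which any panel gene (interneuron / non-neuronal
#' markers) exceeds an FPKM threshold; sorted excitatory-neuron samples
#' should be devoid of such expression.
#'
#' @param expr Expression tibble.
#' @param panel Character vector of panel gene ids.
#' @param threshold FPKM above which a panel gene counts as expressed
#'   (default 10, the expressed-gene cutoff).
#' @return Tibble: `sample_id`, `max_panel_fpkm`, `n_above`, `flagged`; panel
#'   genes absent from the matrix are reported in the `missing_genes`
#'   attribute (with a warning), not fatal.
#' @export
contamination_check <- function(expr, panel, threshold = 10) {
  validate_expression_matrix(expr)
  if (length(panel) == 0) abort("contamination panel is empty")
  m <- as_fpkm_matrix(expr)
  miss <- setdiff(panel, rownames(m))
  if (length(miss) == length(panel)) abort("no panel genes present in the matrix")
  if (length(miss)) {
    warn(paste0("panel genes absent from matrix: ", fmt_ids(miss)))
  }
  pm <- m[intersect(panel, rownames(m)), , drop = FALSE]
  out <- tibble(
    sample_id = colnames(pm),
    max_panel_fpkm = apply(pm, 2, max),
    n_above = colSums(pm > threshold),
    flagged = colSums(pm > threshold) > 0
  )
  attr(out, "missing_genes") <- miss
  attr(out, "threshold") <- threshold
  out
}

#' Full quality-control report
#'
#' Combines whole-transcriptome replicate correlation, spike-in
#' reproducibility, and the contamination purity check into one object with
#' `tidy()`, `glance()` and `autoplot()` methods.
#'
#' @inheritParams replicate_correlation
#' @param panel Contamination panel gene ids; panel genes entirely absent
#'   disable the check with a message.
#' @param spike_pattern Regular expression for spike-in ids; no matches
#'   disables the spike-in check.
#' @param contamination_threshold FPKM threshold for the purity check.
#' @return Object of class `qc_report`.
#' @export
qc_report <- function(expr, meta, panel = default_contamination_panel(),
                      spike_pattern = "^ERCC-", threshold = 0.90,
                      contamination_threshold = 10) {
  biological <- drop_spike_ins(expr, spike_pattern)
  rep_qc <- replicate_correlation(biological, meta, threshold = threshold)
  spike_qc <- if (any(grepl(spike_pattern, expr$gene_id))) {
    spike_in_correlation(expr, meta, pattern = spike_pattern,
                         threshold = threshold)
  }
  cont <- if (any(panel %in% expr$gene_id)) {
    contamination_check(expr, panel, threshold = contamination_threshold)
  }
  structure(list(replicates = rep_qc, spike_ins = spike_qc,
                 contamination = cont, threshold = threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  p <- x$replicates$populations
  cat("QC report:", nrow(p), "populations;",
      sum(p$pass), "pass the all-pairs r >", x$threshold, "gate\n")
  if (!is.null(x$spike_ins)) {
    cat("spike-in mean pairwise r:",
        round(mean(x$spike_ins$pairs$r), 3), "\n")
  }
  if (!is.null(x$contamination)) {
    cat("contamination-flagged samples:",
        sum(x$contamination$flagged), "\n")
  }
  invisible(x)
}
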