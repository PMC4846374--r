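#' Read a genes-by-samples FPKM matrix from delimited text
#'
#' The expected layout mirrors typical Cuffdiff-style exports: a header row of
#' sample identifiers, a first column of gene identifiers, and one non-negative
#' FPKM value per (gene, sample) cell. Gene identifiers are treated as opaque
#' strings; no identifier mapping is attempted.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; tab by default, use `","` for CSV.
#' @return A tibble with a character `gene_id` column followed by one numeric
#'   column per sample, validated by [validate_expression_matrix()].
#' @seealso [write_expression_matrix()], [aggregate_replicates()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(0, 2), s2 = c(1, 3))
#' write_expression_matrix(m, tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) abort("expression matrix needs a gene column plus >= 1 sample column")
  gene_id <- raw[[1]]
  vals <- raw[, -1, drop = FALSE]
  num <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(NULL, names(vals)))
  for (j in seq_along(vals)) {
    x <- trimws(vals[[j]])
    bad <- which(is.na(x) | x == "" | x == "NA")
    if (length(bad)) {
      abort(sprintf("missing cell at gene '%s', sample '%s'",
                    gene_id[bad[1]], names(vals)[j]))
    }
    xn <- suppressWarnings(as.numeric(x))
    nn <- which(is.na(xn))
    if (length(nn)) {
      abort(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                    x[nn[1]], gene_id[nn[1]], names(vals)[j]))
    }
    num[, j] <- xn
  }
  expr <- bind_cols(tibble(gene_id = gene_id), as_tibble(num))
  validate_expression_matrix(expr)
  expr
}

#' Validate an FPKM expression tibble
#'
#' Checks the data-model invariants: a character `gene_id` key with no
#' duplicates, unique sample columns, and dense, finite, non-negative values.
#'
#' @param expr A tibble as returned by [read_expression_matrix()].
#' @return `expr`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(expr) {
  if (!is.data.frame(expr) || names(expr)[1] != "gene_id") {
    abort("expression matrix must be a data frame whose first column is 'gene_id'")
  }
  if (ncol(expr) < 2) abort("expression matrix has no sample columns")
  dup <- unique(expr$gene_id[duplicated(expr$gene_id)])
  if (length(dup)) abort(paste0("duplicated gene id(s): ", fmt_ids(dup)))
  dup_s <- unique(names(expr)[-1][duplicated(names(expr)[-1])])
  if (length(dup_s)) abort(paste0("duplicated sample id(s): ", fmt_ids(dup_s)))
  for (j in names(expr)[-1]) {
    x <- expr[[j]]
    if (!is.numeric(x)) abort(paste0("sample '", j, "' is not numeric"))
    if (anyNA(x)) {
      abort(sprintf("missing cell at gene '%s', sample '%s'",
                    expr$gene_id[which(is.na(x))[1]], j))
    }
    if (any(!is.finite(x))) abort(paste0("non-finite value in sample '", j, "'"))
    if (any(x < 0)) {
      abort(sprintf("negative FPKM at gene '%s', sample '%s'",
                    expr$gene_id[which(x < 0)[1]], j))
    }
  }
  invisible(expr)
}

#' Write an FPKM matrix (or any gene-keyed table) to delimited text
#'
#' Values are serialized with 6 significant digits, matching typical FPKM
#' export precision; [read_expression_matrix()] round-trips such files up to
#' that precision.
#'
#' @param expr Tibble with `gene_id` first and numeric columns after.
#' @param path Output path.
#' @param delim Field delimiter (tab default).
#' @param digits Significant digits for numeric serialization.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, delim = "\t", digits = 6) {
  out <- as.data.frame(expr)
  for (j in seq_along(out)[-1]) {
    out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
  }
  write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' A four-column delimited table: `sample_id`, `cell_class` (one of GC, MC,
#' CA3, CA2, CA1), `region` (dorsal, ventral, or none), `replicate` (positive
#' integer). A (cell_class, region) pair defines a population; classes profiled
#' without a dorsal/ventral split (mossy cells, CA2) use region `none`.
#'
#' @param path Path to delimited text.
#' @param delim Field delimiter.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_class", "region", "replicate")
  if (!all(need %in% names(raw))) {
    abort(paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  }
  meta <- as_tibble(raw[need])
  meta$sample_id <- as.character(meta$sample_id)
  meta$replicate <- as.integer(meta$replicate)
  validate_sample_metadata(meta)
  meta
}

#' Validate a sample-metadata tibble
#'
#' @param meta Metadata tibble (`sample_id`, `cell_class`, `region`,
#'   `replicate`).
#' @param expr Optional expression tibble; if given, the sample sets must
#'   match exactly.
#' @return `meta`, invisibly.
#' @export
validate_sample_metadata <- function(meta, expr = NULL) {
  need <- c("sample_id", "cell_class", "region", "replicate")
  if (!is.data.frame(meta) || !all(need %in% names(meta))) {
    abort(paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  }
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) abort(paste0("duplicated sample id(s) in metadata: ", fmt_ids(dup)))
  bad_c <- setdiff(unique(meta$cell_class), CELL_CLASSES)
  if (length(bad_c)) {
    abort(paste0("unknown cell_class: ", fmt_ids(bad_c),
                 " (expected ", paste(CELL_CLASSES, collapse = ", "), ")"))
  }
  bad_r <- setdiff(unique(meta$region), REGIONS)
  if (length(bad_r)) {
    abort(paste0("unknown region: ", fmt_ids(bad_r),
                 " (expected ", paste(REGIONS, collapse = ", "), ")"))
  }
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1)) {
    abort("replicate must be a positive integer")
  }
  if (!is.null(expr)) {
    s_expr <- names(expr)[-1]
    miss <- setdiff(s_expr, meta$sample_id)
    extra <- setdiff(meta$sample_id, s_expr)
    if (length(miss)) abort(paste0("samples missing from metadata: ", fmt_ids(miss)))
    if (length(extra)) abort(paste0("metadata samples absent from matrix: ", fmt_ids(extra)))
  }
  invisible(meta)
}

#' Population label for each sample
#'
#' A population is a (cell_class, region) pair; samples with region `none`
#' are labelled by cell class alone (e.g. `MC`, `CA2`), the others as e.g.
#' `CA1_dorsal`.
#'
#' @param meta Metadata tibble.
#' @return Character vector, one label per metadata row.
#' @export
population_labels <- function(meta) {
  ifelse(meta$region == "none", meta$cell_class,
         paste(meta$cell_class, meta$region, sep = "_"))
}

#' Average replicate FPKM into a population matrix
#'
#' Collapses the replicate-level matrix to whole-transcriptome averaged FPKM:
#' one column per (cell_class, region) population, each value the arithmetic
#' mean over that population's replicates.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param meta Metadata covering exactly the matrix samples.
#' @return Tibble with `gene_id` plus one numeric column per population, in
#'   order of first appearance in `meta`.
#' @export
aggregate_replicates <- function(expr, meta) {
  validate_expression_matrix(expr)
  validate_sample_metadata(meta, expr)
  m <- as_fpkm_matrix(expr)
  labs <- population_labels(meta)
  pops <- unique(labs)
  out <- matrix(0, nrow(m), length(pops), dimnames = list(rownames(m), pops))
  for (p in pops) {
    ids <- meta$sample_id[labs == p]
    if (!length(ids)) abort(paste0("population with zero samples: ", p))
    out[, p] <- rowMeans(m[, ids, drop = FALSE])
  }
  fpkm_tibble(out)
}

#' Drop ERCC spike-in rows from an expression table
#'
#' Spike-in controls are used only for quantification QC and are excluded
#' from all downstream analyses.
#'
#' @param expr Expression tibble.
#' @param pattern Regular expression identifying spike-in gene ids.
#' @return `expr` without spike-in rows.
#' @export
drop_spike_ins <- function(expr, pattern = "^ERCC-") {
  expr[!grepl(pattern, expr$gene_id), , drop = FALSE]
}
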