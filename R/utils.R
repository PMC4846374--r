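#' Known cell classes and regions
#'
#' Enumerations used throughout the package: the five excitatory cell classes
#' of the hippocampus (dentate granule cells `GC`, hilar mossy cells `MC`, and
#' pyramidal cells of `CA3`, `CA2`, `CA1`) and the region codes (`dorsal`,
#' `ventral`, or `none` for classes profiled without a dorsal/ventral split).
#'
#' @name enumerations
#' @keywords internal
NULL

CELL_CLASSES <- c("GC", "MC", "CA3", "CA2", "CA1")
REGIONS <- c("dorsal", "ventral", "none")

# Derive a 31-bit stream seed from a base seed plus small stream indices.
# Keeping streams separate means planting extra structure never perturbs the
# background draws.
stream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}

# Convert a gene_id-keyed tibble (gene_id + numeric sample columns) to a
# numeric matrix with gene rownames.
as_fpkm_matrix <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "gene_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

# Inverse of as_fpkm_matrix().
fpkm_tibble <- function(m) {
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

row_max <- function(m) apply(m, 1L, max)
row_min <- function(m) apply(m, 1L, min)

fmt_ids <- function(x, max = 5L) {
  if (length(x) > max) {
    paste0(paste(head(x, max), collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
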