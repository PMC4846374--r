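#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-unit table (one row per replicate pair, per pole, per gene, per
#' item), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name hippoexpr-tidiers
NULL

#' @rdname hippoexpr-tidiers
#' @export
tidy.qc_correlation <- function(x, ...) x$pairs

#' @rdname hippoexpr-tidiers
#' @export
glance.qc_correlation <- function(x, ...) {
  tibble(n_populations = nrow(x$populations),
         n_pass = sum(x$populations$pass),
         mean_r = mean(x$pairs$r),
         min_r = suppressWarnings(min(x$pairs$r)),
         threshold = x$threshold)
}

#' @rdname hippoexpr-tidiers
#' @export
tidy.qc_report <- function(x, ...) {
  out <- mutate(x$replicates$pairs, block = "transcriptome")
  if (!is.null(x$spike_ins)) {
    out <- bind_rows(out, mutate(x$spike_ins$pairs, block = "spike_in"))
  }
  out
}

#' @rdname hippoexpr-tidiers
#' @export
glance.qc_report <- function(x, ...) {
  g <- glance(x$replicates)
  g$spike_in_mean_r <- if (!is.null(x$spike_ins)) mean(x$spike_ins$pairs$r) else NA_real_
  g$n_contaminated <- if (!is.null(x$contamination)) {
    sum(x$contamination$flagged)
  } else {
    NA_integer_
  }
  g
}

#' @rdname hippoexpr-tidiers
#' @export
tidy.overlap_null <- function(x, ...) x$results

#' @rdname hippoexpr-tidiers
#' @export
glance.overlap_null <- function(x, ...) {
  row <- if ("combined" %in% x$results$pole) {
    x$results[x$results$pole == "combined", ]
  } else {
    x$results[1, ]
  }
  select(row, "observed", "null_mean", "null_sd", "p_empirical", "p_normal",
         "n_reps", "seed")
}

#' @rdname hippoexpr-tidiers
#' @export
tidy.module_set <- function(x, ...) x$assignment

#' @rdname hippoexpr-tidiers
#' @export
glance.module_set <- function(x, ...) {
  sizes <- table(x$assignment$module)
  tibble(n_modules = x$k, n_genes = nrow(x$assignment),
         min_size = min(sizes), max_size = max(sizes),
         cut_height = x$height %||% NA_real_)
}

#' @rdname hippoexpr-tidiers
#' @export
tidy.mds_result <- function(x, ...) x$points

#' @rdname hippoexpr-tidiers
#' @export
glance.mds_result <- function(x, ...) {
  pos <- x$eig[x$eig > 0]
  k <- ncol(x$points) - 1
  tibble(n_items = nrow(x$points), k = k,
         goodness_of_fit = sum(sort(pos, decreasing = TRUE)[seq_len(min(k, length(pos)))]) /
           sum(abs(x$eig)))
}
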