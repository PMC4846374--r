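#' Cross-class overlap scenario
#'
#' Bundles, per cell class, the expressed-gene universe and the dorsal- and/or
#' ventral-enriched gene lists, for overlap counting and the Monte Carlo
#' null. Enriched lists must be subsets of their universes and the two pole
#' lists of a class must be disjoint.
#'
#' @param universes Named list (one element per class) of expressed-gene
#'   character vectors.
#' @param dorsal,ventral Named lists of enriched gene ids per class; at least
#'   one pole must be supplied, and names must match `universes`.
#' @return Object of class `overlap_scenario`.
#' @seealso [build_overlap_scenario()] to derive one from a population
#'   matrix, [monte_carlo_null()].
#' @export
overlap_scenario <- function(universes, dorsal = NULL, ventral = NULL) {
  if (is.null(names(universes)) || any(names(universes) == "")) {
    abort("universes must be a named list of gene vectors")
  }
  poles <- list(dorsal = dorsal, ventral = ventral)
  poles <- poles[!vapply(poles, is.null, logical(1))]
  if (!length(poles)) abort("supply enriched lists for at least one pole")
  for (pn in names(poles)) {
    pl <- poles[[pn]]
    miss <- setdiff(names(pl), names(universes))
    if (length(miss)) abort(paste0("enriched lists for unknown class: ", fmt_ids(miss)))
    for (cl in names(pl)) {
      out <- setdiff(pl[[cl]], universes[[cl]])
      if (length(out)) {
        abort(sprintf("%s %s enriched genes outside the universe: %s",
                      cl, pn, fmt_ids(out)))
      }
    }
  }
  both <- intersect(names(poles$dorsal %||% list()), names(poles$ventral %||% list()))
  for (cl in both) {
    clash <- intersect(poles$dorsal[[cl]], poles$ventral[[cl]])
    if (length(clash)) {
      abort(paste0("genes enriched at both poles in ", cl, ": ", fmt_ids(clash)))
    }
  }
  structure(list(universes = universes, enriched = poles),
            class = "overlap_scenario")
}

#' Derive an overlap scenario from a population matrix
#'
#' Runs [pole_enriched_genes()] for each class and collects per-class
#' expressed universes (FPKM above threshold in at least one of the class's
#' two pole populations) together with the dorsal and ventral enriched lists.
#'
#' @param pop Population-mean tibble.
#' @param classes Cell classes with both poles profiled.
#' @param fold Pole-enrichment factor.
#' @param expressed_threshold Expressed-gene FPKM cutoff.
#' @return An [overlap_scenario()].
#' @export
build_overlap_scenario <- function(pop, classes = c("GC", "CA3", "CA1"),
                                   fold = 2, expressed_threshold = 10) {
  universes <- list(); dorsal <- list(); ventral <- list()
  for (cl in classes) {
    enr <- pole_enriched_genes(pop, cl, fold = fold,
                               expressed_threshold = expressed_threshold)
    universes[[cl]] <- attr(enr, "universe")
    dorsal[[cl]] <- enr$gene_id[enr$pole == "dorsal"]
    ventral[[cl]] <- enr$gene_id[enr$pole == "ventral"]
  }
  overlap_scenario(universes, dorsal = dorsal, ventral = ventral)
}

#' Observed overlap of enriched gene lists
#'
#' Size of the intersection of the chosen classes' enriched lists at one
#' pole.
#'
#' @param scenario An [overlap_scenario()].
#' @param classes Classes to intersect (default: all in the scenario).
#' @param pole `"dorsal"` or `"ventral"`.
#' @return Integer count.
#' @export
overlap_counts <- function(scenario, classes = NULL, pole = "dorsal") {
  stopifnot(inherits(scenario, "overlap_scenario"))
  pl <- scenario$enriched[[pole]]
  if (is.null(pl)) abort(paste0("scenario has no ", pole, " enriched lists"))
  classes <- classes %||% names(pl)
  miss <- setdiff(classes, names(pl))
  if (length(miss)) abort(paste0("class absent from scenario: ", fmt_ids(miss)))
  length(Reduce(intersect, pl[classes]))
}

#' Monte Carlo null for cross-class overlap of enriched genes
#'
#' For each replicate and each class, draws as many genes as that class's
#' enriched list, uniformly without replacement from that class's own
#' expressed universe, and records the intersection size across classes. The
#' empirical p uses the add-one estimator `(1 + #(null >= observed)) /
#' (1 + n_reps)` and is reported as an upper bound when no null draw reaches
#' the observed count; a normal-approximation upper-tail p from
#' `z = (observed - null mean) / null sd` is reported alongside, since an
#' empirical p from a finite replicate count cannot go below
#' `1 / (n_reps + 1)`. Draws are seeded per (replicate, class), so they are
#' independent of evaluation order and bit-reproducible.
#'
#' For two classes sharing one universe of size N this null is hypergeometric:
#' mean `n1 n2 / N`, variance `n1 n2 (N - n1)(N - n2) / (N^2 (N - 1))`.
#'
#' @param scenario An [overlap_scenario()].
#' @param classes Classes to test (default: all with lists at each pole).
#' @param n_reps Number of Monte Carlo replicates (default 1000).
#' @param seed Integer seed.
#' @return Object of class `overlap_null`: `results` tibble (one row per
#'   pole plus a `combined` row summing the dorsal and ventral counts) with
#'   observed, null_mean, null_sd, p_empirical, p_empirical_label, p_normal;
#'   and `null_draws`, a named list of integer vectors of length `n_reps`.
#' @export
monte_carlo_null <- function(scenario, classes = NULL, n_reps = 1000, seed = 1) {
  stopifnot(inherits(scenario, "overlap_scenario"))
  if (n_reps < 1) abort("n_reps must be >= 1")
  poles <- names(scenario$enriched)
  all_genes <- unique(unlist(scenario$universes))
  draws <- list()
  obs <- numeric(0)
  for (pn in poles) {
    pl <- scenario$enriched[[pn]]
    cls <- classes %||% names(pl)
    miss <- setdiff(cls, names(pl))
    if (length(miss)) abort(paste0("class absent from scenario: ", fmt_ids(miss)))
    univ_codes <- lapply(scenario$universes[cls], match, table = all_genes)
    k <- vapply(pl[cls], length, integer(1))
    for (ci in seq_along(cls)) {
      if (k[ci] > length(univ_codes[[ci]])) {
        abort(sprintf("%s: enriched list (%d) larger than universe (%d)",
                      cls[ci], k[ci], length(univ_codes[[ci]])))
      }
    }
    obs[pn] <- overlap_counts(scenario, cls, pn)
    nb <- length(all_genes)
    pole_idx <- match(pn, c("dorsal", "ventral"))
    null <- integer(n_reps)
    for (r in seq_len(n_reps)) {
      cnt <- integer(nb)
      for (ci in seq_along(cls)) {
        set.seed(stream_seed(seed, pole_idx, r, ci))
        pick <- univ_codes[[ci]][sample.int(length(univ_codes[[ci]]), k[ci])]
        cnt[pick] <- cnt[pick] + 1L
      }
      null[r] <- sum(cnt == length(cls))
    }
    draws[[pn]] <- null
  }
  if (length(poles) == 2) {
    draws$combined <- draws$dorsal + draws$ventral
    obs["combined"] <- obs["dorsal"] + obs["ventral"]
  }
  res <- lapply(names(draws), function(pn) {
    null <- draws[[pn]]
    o <- unname(obs[[pn]])
    mu <- mean(null); s <- sd(null)
    n_ge <- sum(null >= o)
    p_emp <- (1 + n_ge) / (1 + n_reps)
    z <- if (s > 0) (o - mu) / s else NA_real_
    tibble(pole = pn, observed = o, null_mean = mu, null_sd = s,
           p_empirical = p_emp,
           p_empirical_label = if (n_ge == 0) {
             sprintf("< %.3g", 1 / (n_reps + 1))
           } else {
             sprintf("%.3g", p_emp)
           },
           p_normal = if (is.na(z)) NA_real_ else pnorm(z, lower.tail = FALSE),
           n_reps = n_reps, seed = seed)
  }) |> bind_rows()
  structure(list(results = res, null_draws = draws,
                 classes = classes %||% names(scenario$enriched[[poles[1]]])),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat("Monte Carlo overlap null over classes:",
      paste(x$classes, collapse = ", "), "\n")
  print(x$results, ...)
  invisible(x)
}

#' Directional concordance with an external enriched-gene list
#'
#' Counts how many internally pole-enriched genes appear in an external
#' differential-expression list with the same pole of enrichment.
#'
#' @param internal Tibble with `gene_id` and `pole` columns (e.g. the output
#'   of [pole_enriched_genes()]).
#' @param external Tibble with `gene_id` and `pole`; one pole per gene
#'   (conflicting duplicates are an error).
#' @return Tibble with one row per pole plus an `overall` row: `n_matched`,
#'   `n_total`, `fraction`.
#' @export
directional_concordance <- function(internal, external) {
  need <- c("gene_id", "pole")
  if (!all(need %in% names(internal)) || !all(need %in% names(external))) {
    abort("internal and external need 'gene_id' and 'pole' columns")
  }
  ext <- unique(external[need])
  dup <- unique(ext$gene_id[duplicated(ext$gene_id)])
  if (length(dup)) {
    abort(paste0("external genes with conflicting poles: ", fmt_ids(dup)))
  }
  matched <- internal$gene_id %in% ext$gene_id &
    ext$pole[match(internal$gene_id, ext$gene_id)] == internal$pole
  per_pole <- tibble(pole = internal$pole, matched = matched) |>
    group_by(.data$pole) |>
    summarise(n_matched = sum(.data$matched), n_total = n(), .groups = "drop")
  bind_rows(per_pole,
            tibble(pole = "overall", n_matched = sum(matched),
                   n_total = nrow(internal))) |>
    mutate(fraction = ifelse(.data$n_total > 0,
                             .data$n_matched / .data$n_total, 0))
}
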