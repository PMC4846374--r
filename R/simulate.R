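#' Default population design: eight sorted populations
#'
#' Granule cells, CA3 and CA1 pyramidal cells at both dorsal and ventral
#' poles, plus mossy cells and CA2 pyramidal cells profiled without a
#' regional split.
#'
#' @return Tibble with `cell_class` and `region` columns (8 rows).
#' @export
default_populations <- function() {
  tibble(
    cell_class = c("GC", "GC", "MC", "CA3", "CA3", "CA2", "CA1", "CA1"),
    region     = c("dorsal", "ventral", "none", "dorsal", "ventral", "none",
                   "dorsal", "ventral")
  )
}

#' Default interneuron / non-neuronal contamination panel
#'
#' Marker genes of interneurons (Gad1, Gad2, Sst, Pvalb, Vip), astrocytes
#' (Gfap, Aqp4), oligodendrocytes (Mbp, Plp1), microglia (Cx3cr1, Aif1) and
#' endothelium (Cldn5). Pure excitatory-neuron samples should express none of
#' them appreciably.
#'
#' @return Character vector of gene symbols.
#' @export
default_contamination_panel <- function() {
  c("Gad1", "Gad2", "Sst", "Pvalb", "Vip", "Gfap", "Aqp4",
    "Mbp", "Plp1", "Cx3cr1", "Aif1", "Cldn5")
}

default_class_markers <- function() {
  list(
    list(classes = "GC",  fold = 10, count = 300),
    list(classes = "MC",  fold = 8,  count = 200),
    list(classes = "CA3", fold = 5,  count = 100),
    list(classes = "CA2", fold = 5,  count = 100),
    list(classes = "CA1", fold = 5,  count = 100)
  )
}

default_region_genes <- function() {
  shared <- c("GC", "CA3", "CA1")
  c(
    list(list(pole = "dorsal",  fold = 3, count = 30, classes = shared),
         list(pole = "ventral", fold = 3, count = 30, classes = shared)),
    unlist(lapply(shared, function(cl) {
      list(list(pole = "dorsal",  fold = 3, count = 80, classes = cl),
           list(pole = "ventral", fold = 3, count = 80, classes = cl))
    }), recursive = FALSE)
  )
}

default_modules <- function() {
  prof <- function(pops, mult = 6) setNames(rep(mult, length(pops)), pops)
  list(
    list(name = "GC",        profile = prof(c("GC_dorsal", "GC_ventral")),   count = 40),
    list(name = "MC",        profile = prof("MC"),                            count = 40),
    list(name = "CA3",       profile = prof(c("CA3_dorsal", "CA3_ventral")), count = 40),
    list(name = "CA2",       profile = prof("CA2"),                           count = 40),
    list(name = "CA1",       profile = prof(c("CA1_dorsal", "CA1_ventral")), count = 40),
    list(name = "pyramidal", profile = prof(c("CA3_dorsal", "CA3_ventral",
                                              "CA2", "CA1_dorsal",
                                              "CA1_ventral"), 4),            count = 40),
    list(name = "dorsal",    profile = prof(c("GC_dorsal", "CA3_dorsal",
                                              "CA1_dorsal"), 4),             count = 40),
    list(name = "ventral",   profile = prof(c("GC_ventral", "CA3_ventral",
                                              "CA1_ventral"), 4),            count = 40)
  )
}

#' Configuration for the synthetic FPKM generator
#'
#' Defines the replicate design and every planted feature. Defaults emulate
#' the profiled study design: 8 populations x 3 biological replicates,
#' log10-normal baseline expression, multiplicative lognormal replicate noise
#' calibrated so that within-population replicate correlation on raw FPKM is
#' about 0.98, planted class markers and dorsal/ventral genes at fixed fold
#' changes, eight co-expression modules, an ERCC-like spike-in ladder, and a
#' contamination panel that is silent unless leakage is requested.
#'
#' @param n_genes Total number of genes (planted features included).
#' @param populations Tibble of (cell_class, region) pairs.
#' @param n_replicates Biological replicates per population.
#' @param baseline_log10_mean,baseline_log10_sd Normal parameters of per-gene
#'   log10 baseline FPKM.
#' @param marker_floor_fpkm Baseline floor applied to planted differential
#'   genes (class markers, region genes, module members). A marker whose
#'   target expression fell below the expressed-gene filter would be
#'   undetectable by construction; reported markers are expressed by
#'   definition.
#' @param replicate_cv Coefficient of variation of multiplicative lognormal
#'   replicate noise. The default 0.14 is the closed-form value at which two
#'   replicates sharing lognormal gene means (log10 sd 0.8) have raw-FPKM
#'   Pearson correlation ~ 0.98.
#' @param class_markers List of `list(classes, fold, count)`: genes whose
#'   mean is multiplied by `fold` in every population of the named classes.
#' @param region_genes List of `list(pole, fold, count, classes)`: genes whose
#'   mean is multiplied by `fold` in the named pole of the affected classes.
#' @param modules List of `list(name, profile, count)`; `profile` is a named
#'   vector of per-population multipliers (unnamed populations get 1).
#' @param contamination `list(genes, leakage, n_samples, source_fpkm)`: the
#'   panel genes have zero baseline; if `leakage > 0`, `n_samples` randomly
#'   chosen samples express them at `leakage * source_fpkm`.
#' @param spike_ins `list(n, log10_min, log10_max, cv)`: a deterministic
#'   concentration ladder identical across samples up to replicate noise.
#' @param seed Integer seed; all randomness is derived from it via independent
#'   streams, so the same seed gives bit-identical output and planting extra
#'   features does not perturb background values.
#' @return Object of class `sim_config`.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_genes = 5000,
                       populations = default_populations(),
                       n_replicates = 3,
                       baseline_log10_mean = 1.0,
                       baseline_log10_sd = 0.8,
                       marker_floor_fpkm = 15,
                       replicate_cv = 0.14,
                       class_markers = default_class_markers(),
                       region_genes = default_region_genes(),
                       modules = default_modules(),
                       contamination = list(genes = default_contamination_panel(),
                                            leakage = 0, n_samples = 0,
                                            source_fpkm = 100),
                       spike_ins = list(n = 92, log10_min = -1, log10_max = 3,
                                        cv = 0.25),
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), populations = populations,
              n_replicates = as.integer(n_replicates),
              baseline_log10_mean = baseline_log10_mean,
              baseline_log10_sd = baseline_log10_sd,
              marker_floor_fpkm = marker_floor_fpkm,
              replicate_cv = replicate_cv,
              class_markers = class_markers %||% list(),
              region_genes = region_genes %||% list(),
              modules = modules %||% list(),
              contamination = contamination,
              spike_ins = spike_ins,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  folds <- c(vapply(cfg$class_markers, `[[`, numeric(1), "fold"),
             vapply(cfg$region_genes, `[[`, numeric(1), "fold"))
  if (any(folds <= 1)) abort("planted folds must be > 1")
  if (cfg$replicate_cv < 0) abort("replicate_cv must be >= 0")
  lk <- cfg$contamination$leakage %||% 0
  if (lk < 0 || lk >= 1) abort("contamination leakage must be in [0, 1)")
  n_planted <- sum(vapply(cfg$class_markers, `[[`, numeric(1), "count"),
                   vapply(cfg$region_genes, `[[`, numeric(1), "count"),
                   vapply(cfg$modules, `[[`, numeric(1), "count")) +
    length(cfg$contamination$genes %||% character()) +
    (cfg$spike_ins$n %||% 0)
  if (n_planted > cfg$n_genes) {
    abort(sprintf("planted gene counts (%d) exceed n_genes (%d)",
                  n_planted, cfg$n_genes))
  }
  pops <- population_labels(cfg$populations |> rename_pop_cols())
  bad <- setdiff(unlist(lapply(cfg$modules, function(m) names(m$profile))), pops)
  if (length(bad)) abort(paste0("module profile names unknown populations: ", fmt_ids(bad)))
  invisible(cfg)
}

# populations tibble uses cell_class/region directly; reuse population_labels()
rename_pop_cols <- function(pops) {
  tibble(sample_id = NA_character_, cell_class = pops$cell_class,
         region = pops$region, replicate = 1L)
}

#' Generate a replicate-structured synthetic FPKM dataset
#'
#' Per-gene baseline FPKM is drawn log10-normal; planted features multiply
#' population means before noise (so noiseless folds are exact); replicate
#' values are the population mean times mean-one multiplicative lognormal
#' noise. Spike-ins follow a fixed concentration ladder shared by all
#' samples; contamination-panel genes are exactly zero unless leakage is
#' configured. Background genes have identical means in every population
#' (exchangeable), so all between-population structure is planted and
#' recorded in the manifest.
#'
#' @param config A [sim_config()].
#' @return A list of class `hippo_sim` with elements `expression` (tibble,
#'   gene_id + one column per sample), `metadata` (sample metadata tibble),
#'   and `manifest` (list: `genes` tibble with one role per gene,
#'   `contaminated_samples`, `config`).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 300, seed = 42,
#'   class_markers = list(list(classes = "CA2", fold = 4, count = 10)),
#'   region_genes = NULL, modules = NULL))
#' dim(sim$expression)
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  pops <- population_labels(rename_pop_cols(config$populations))
  n_pops <- length(pops)
  meta <- tibble(
    sample_id  = paste(rep(pops, each = config$n_replicates),
                       rep(seq_len(config$n_replicates), n_pops), sep = "_"),
    cell_class = rep(config$populations$cell_class, each = config$n_replicates),
    region     = rep(config$populations$region, each = config$n_replicates),
    replicate  = rep(seq_len(config$n_replicates), n_pops)
  )
  ng <- config$n_genes

  # --- role assignment (deterministic block layout) ---
  roles <- tibble(gene_id = sprintf("G%05d", seq_len(ng)),
                  role = "background", target = NA_character_,
                  fold = NA_real_, module = NA_character_)
  cursor <- 0L
  take <- function(k) (cursor + 1L):(cursor + k)
  for (cm in config$class_markers) {
    idx <- take(cm$count); cursor <- cursor + cm$count
    roles$role[idx] <- "class_marker"
    roles$target[idx] <- paste(cm$classes, collapse = "+")
    roles$fold[idx] <- cm$fold
  }
  for (rg in config$region_genes) {
    idx <- take(rg$count); cursor <- cursor + rg$count
    roles$role[idx] <- "region_gene"
    roles$target[idx] <- paste0(rg$pole, ":", paste(rg$classes, collapse = "+"))
    roles$fold[idx] <- rg$fold
  }
  for (md in config$modules) {
    idx <- take(md$count); cursor <- cursor + md$count
    roles$role[idx] <- "module_member"
    roles$module[idx] <- md$name
  }
  panel <- config$contamination$genes %||% character()
  if (length(panel)) {
    idx <- take(length(panel)); cursor <- cursor + length(panel)
    roles$role[idx] <- "contamination"
    roles$gene_id[idx] <- panel
  }
  n_spike <- config$spike_ins$n %||% 0L
  if (n_spike > 0) {
    idx <- take(n_spike); cursor <- cursor + n_spike
    roles$role[idx] <- "spike_in"
    roles$gene_id[idx] <- sprintf("ERCC-%03d", seq_len(n_spike))
  }

  # --- population mean matrix ---
  set.seed(stream_seed(config$seed, 1L))
  base <- 10 ^ rnorm(ng, config$baseline_log10_mean, config$baseline_log10_sd)
  planted <- roles$role %in% c("class_marker", "region_gene", "module_member")
  base[planted] <- pmax(base[planted], config$marker_floor_fpkm)
  base[roles$role == "contamination"] <- 0
  if (n_spike > 0) {
    base[roles$role == "spike_in"] <-
      10 ^ seq(config$spike_ins$log10_min, config$spike_ins$log10_max,
               length.out = n_spike)
  }
  M <- matrix(base, ng, n_pops, dimnames = list(roles$gene_id, pops))
  cursor <- 0L
  for (cm in config$class_markers) {
    idx <- take(cm$count); cursor <- cursor + cm$count
    tgt <- pops[config$populations$cell_class %in% cm$classes]
    M[idx, tgt] <- M[idx, tgt] * cm$fold
  }
  for (rg in config$region_genes) {
    idx <- take(rg$count); cursor <- cursor + rg$count
    tgt <- pops[config$populations$cell_class %in% rg$classes &
                  config$populations$region == rg$pole]
    if (!length(tgt)) abort(paste0("region genes target no population: ", rg$pole))
    M[idx, tgt] <- M[idx, tgt] * rg$fold
  }
  for (md in config$modules) {
    idx <- take(md$count); cursor <- cursor + md$count
    mult <- rep(1, n_pops)
    mult[match(names(md$profile), pops)] <- md$profile
    M[idx, ] <- sweep(M[idx, , drop = FALSE], 2, mult, `*`)
  }

  # --- replicate expansion with mean-one lognormal noise ---
  n_samples <- nrow(meta)
  pop_of_sample <- population_labels(meta)
  S <- M[, pop_of_sample, drop = FALSE]
  colnames(S) <- meta$sample_id
  sdlog <- rep(sqrt(log1p(config$replicate_cv^2)), ng)
  sdlog[roles$role == "spike_in"] <- sqrt(log1p((config$spike_ins$cv %||% 0)^2))
  if (any(sdlog > 0)) {
    set.seed(stream_seed(config$seed, 2L))
    eps <- matrix(rnorm(ng * n_samples), ng, n_samples)
    S <- S * exp(eps * sdlog - sdlog^2 / 2)
  }

  # --- contamination leakage ---
  contaminated <- character()
  lk <- config$contamination$leakage %||% 0
  n_cont <- config$contamination$n_samples %||% 0
  if (lk > 0 && n_cont > 0 && length(panel)) {
    set.seed(stream_seed(config$seed, 3L))
    contaminated <- sort(sample(meta$sample_id, min(n_cont, n_samples)))
    src <- config$contamination$source_fpkm %||% 100
    set.seed(stream_seed(config$seed, 4L))
    noise <- matrix(rnorm(length(panel) * length(contaminated)),
                    length(panel), length(contaminated))
    s0 <- sqrt(log1p(config$replicate_cv^2))
    S[match(panel, roles$gene_id), contaminated] <-
      lk * src * exp(noise * s0 - s0^2 / 2)
  }

  expr <- fpkm_tibble(S)
  validate_expression_matrix(expr)
  out <- list(expression = expr, metadata = meta,
              manifest = list(genes = roles,
                              contaminated_samples = contaminated,
                              config = config))
  class(out) <- "hippo_sim"
  out
}

#' Genes planted for a given role
#'
#' Convenience accessor over the ground-truth manifest.
#'
#' @param sim A `hippo_sim` object.
#' @param role One of `background`, `class_marker`, `region_gene`,
#'   `module_member`, `contamination`, `spike_in`.
#' @param target Optional target string to match (e.g. `"CA2"` for class
#'   markers, `"dorsal:GC"` for region genes); matched against the manifest
#'   `target` field.
#' @return Character vector of gene ids.
#' @export
planted_genes <- function(sim, role, target = NULL) {
  g <- sim$manifest$genes
  keep <- g$role == role
  if (!is.null(target)) keep <- keep & !is.na(g$target) & g$target == target
  g$gene_id[keep]
}

#' Construct gene lists with a known cross-class overlap
#'
#' Builds per-class expressed-gene universes and pole-enriched gene lists
#' whose k-way intersection is exactly `n_shared`, for testing the overlap
#' counting and its Monte Carlo null against ground truth. Non-shared
#' enriched genes are disjoint across classes; universes share a common
#' background pool (expressed genes largely overlap between related cell
#' classes).
#'
#' @param n_expressed Integer vector (recycled across classes): universe sizes.
#' @param n_enriched Integer vector: enriched-list sizes per class.
#' @param n_shared Number of genes enriched in every class.
#' @param classes Class labels.
#' @param pole Which pole the enriched lists represent.
#' @param seed Integer seed (order shuffling only; membership is exact).
#' @return List with `scenario` (an [overlap_scenario()]) and `manifest`
#'   (shared genes and per-class enriched lists).
#' @export
plant_overlap_scenario <- function(n_expressed, n_enriched, n_shared,
                                   classes = c("GC", "CA3", "CA1"),
                                   pole = "dorsal", seed = 1) {
  k <- length(classes)
  n_expressed <- rep_len(as.integer(n_expressed), k)
  n_enriched <- rep_len(as.integer(n_enriched), k)
  if (n_shared > min(n_enriched)) {
    abort("n_shared cannot exceed the smallest enriched list")
  }
  if (any(n_enriched > n_expressed)) {
    abort("each enriched list must fit inside its expressed universe")
  }
  shared <- if (n_shared > 0) sprintf("shared%05d", seq_len(n_shared)) else character()
  set.seed(stream_seed(seed, 7L))
  cursor <- 0L
  enriched <- setNames(vector("list", k), classes)
  for (i in seq_len(k)) {
    extra <- n_enriched[i] - n_shared
    own <- if (extra > 0) sprintf("enr%05d", cursor + seq_len(extra)) else character()
    cursor <- cursor + extra
    enriched[[i]] <- sample(c(shared, own))
  }
  n_bg <- max(n_expressed - n_enriched)
  bg <- if (n_bg > 0) sprintf("bg%05d", seq_len(n_bg)) else character()
  universes <- setNames(vector("list", k), classes)
  for (i in seq_len(k)) {
    fill <- head(bg, n_expressed[i] - n_enriched[i])
    universes[[i]] <- sample(c(enriched[[i]], fill))
  }
  enr_arg <- setNames(list(enriched), pole)
  sc <- do.call(overlap_scenario, c(list(universes = universes), enr_arg))
  list(scenario = sc,
       manifest = list(shared = shared, enriched = enriched,
                       pole = pole, seed = seed))
}
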