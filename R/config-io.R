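#' Read a pipeline configuration from JSON or YAML
#'
#' Builds a [pipeline_config()] from a flat configuration file. Recognized
#' keys are the arguments of [pipeline_config()] (e.g. `out_dir`, `stages`,
#' `seed`, thresholds, `expression_path`/`metadata_path`), plus an optional
#' `sim` block whose scalar keys are passed to [sim_config()] (e.g.
#' `n_genes`, `n_replicates`, `replicate_cv`, `seed`); planted-structure
#' lists beyond the defaults are constructed in code, not in config files.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @param out_dir Overrides the file's `out_dir` when given.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim_args <- raw$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad)) abort(paste0("unknown sim config key(s): ", fmt_ids(bad)))
  raw$sim <- NULL
  args <- raw
  if (!is.null(out_dir)) args$out_dir <- out_dir
  bad <- setdiff(names(args), names(formals(pipeline_config)))
  if (length(bad)) abort(paste0("unknown pipeline config key(s): ", fmt_ids(bad)))
  if (length(sim_args)) args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, args)
}
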