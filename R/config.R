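#' Pipeline configuration
#'
#' Collects every threshold and hyperparameter of the training pipeline in
#' one validated object. Defaults encode the published operating point of
#' the method: a gene is usable when it reaches 100 reads in at least 1% of
#' samples in both the training and validation datasets; genes whose
#' adjusted and unadjusted expression correlate below R = 0.9 are discarded
#' as confounder-dominated; panel genes must be mutually decorrelated below
#' |R| = 0.3; the centroid panel holds 45 genes; proximity and exclusivity
#' are gated at 50%; driver-gene combinations need at least 5 training
#' cases.
#'
#' @param usable_min_count minimum read count for the usability rule.
#' @param usable_min_fraction minimum fraction of samples reaching
#'   `usable_min_count` (ceiling, floor of one sample).
#' @param stability_r minimum adjusted-vs-unadjusted Pearson correlation for
#'   a gene to be considered stable.
#' @param prune_r correlation threshold for greedy panel pruning; a
#'   candidate is rejected when `|R| >= prune_r` against any selected gene.
#' @param panel_size number of genes in the classifier panel.
#' @param proximity_threshold minimum calibrated proximity for a
#'   classifiable sample.
#' @param exclusivity_threshold minimum exclusivity for an unambiguous call.
#' @param min_combo_cases minimum training cases for a driver-gene
#'   combination category.
#' @param n_surrogates number of within-batch surrogate directions removed.
#' @param winsor_limit winsorization bound for standardized expression, in
#'   robust Z units.
#' @param seed integer seed used by any stochastic pipeline step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(usable_min_count = 100L,
                            usable_min_fraction = 0.01,
                            stability_r = 0.9,
                            prune_r = 0.3,
                            panel_size = 45L,
                            proximity_threshold = 0.5,
                            exclusivity_threshold = 0.5,
                            min_combo_cases = 5L,
                            n_surrogates = 5L,
                            winsor_limit = 3.0,
                            seed = 1L) {
  cfg <- list(
    usable_min_count = as.integer(usable_min_count),
    usable_min_fraction = usable_min_fraction,
    stability_r = stability_r,
    prune_r = prune_r,
    panel_size = as.integer(panel_size),
    proximity_threshold = proximity_threshold,
    exclusivity_threshold = exclusivity_threshold,
    min_combo_cases = as.integer(min_combo_cases),
    n_surrogates = as.integer(n_surrogates),
    winsor_limit = winsor_limit,
    seed = as.integer(seed)
  )
  fracs <- c("usable_min_fraction", "proximity_threshold", "exclusivity_threshold")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      stop(sprintf("%s must lie in (0, 1)", f))
    }
  }
  if (cfg$usable_min_count < 1L || cfg$panel_size < 1L || cfg$min_combo_cases < 1L) {
    stop("counts and sizes must be >= 1")
  }
  if (cfg$n_surrogates < 0L) stop("n_surrogates must be >= 0")
  if (cfg$stability_r <= 0 || cfg$stability_r > 1) stop("stability_r must lie in (0, 1]")
  if (cfg$prune_r < 0 || cfg$prune_r > 1) stop("prune_r must lie in [0, 1]")
  if (cfg$winsor_limit <= 0) stop("winsor_limit must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any subset of the [pipeline_config()] fields may be given; unspecified
#' fields keep their defaults. Unknown keys are an error so that typos in a
#' config file cannot silently revert a threshold to its default.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("leukotype pipeline configuration\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
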