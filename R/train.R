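#' Train the calibrated centroid classifier
#'
#' Runs the full training pipeline on a raw count matrix: gene usability
#' filtering (against a validation dataset when available), median-of-ratios
#' normalization and log2 transform, within-batch surrogate removal,
#' matched-subset batch alignment, the adjusted-vs-unadjusted stability
#' filter, robust standardization (parameters frozen for unseen samples),
#' Welch-Z/variance gene ranking with greedy decorrelation pruning, and
#' centroid + probit-calibration fitting for the subtype panel, the
#' driver-gene combination panel and, when reference profiles are supplied,
#' the tissue panel.
#'
#' The validation dataset takes part only in the usability filter (a gene
#' must be expressed in both datasets to be a usable biomarker); feature
#' selection and model fitting see training data only.
#'
#' @param counts training count matrix (genes x samples).
#' @param annotations annotation data frame covering the training samples.
#' @param config a [pipeline_config()].
#' @param val_counts optional validation count matrix for the usability
#'   filter.
#' @param tissue_ref optional tissue reference: a list with `expr` (log2
#'   expression matrix, genes x reference samples) and `labels` (tissue
#'   group per reference sample), e.g. from [simulate_tissue_reference()].
#' @param verbose print stage-by-stage progress to stderr.
#' @return a `centroid_model`: frozen standardization parameters restricted
#'   to the panel genes, the gene panel, per-category centroids and probit
#'   calibrations for each panel, thresholds and training metadata. The
#'   model is serializable with [save_model()].
#' @export
train_classifier <- function(counts, annotations, config = pipeline_config(),
                             val_counts = NULL, tissue_ref = NULL,
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  validate_counts(counts)
  ann <- annotations[match(colnames(counts), annotations$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotations missing for some training samples")

  usable <- filter_usable_genes(counts, val_counts %||% counts, config)
  say("usable genes: %d / %d", length(usable), nrow(counts))
  if (length(usable) < config$panel_size) stop("too few usable genes to build a panel")
  counts_u <- counts[usable, , drop = FALSE]

  sf <- size_factors(counts_u)
  expr0 <- normalize_log2(counts_u, sf)

  sv <- remove_surrogates(expr0, ann, config$n_surrogates)
  matched <- match_subsets(ann)
  ab <- align_batches(sv, matched, ann)
  say("batch alignment: %d matched groups, %d genes excluded as perfectly aligned",
      length(matched$groups), nrow(ab$batch_model$excluded_genes))

  unadj <- expr0[rownames(ab$expr), , drop = FALSE]
  stable <- stability_filter(ab$expr, unadj, config$stability_r)
  say("stable genes: %d / %d", length(stable), nrow(ab$expr))
  if (length(stable) < config$panel_size) stop("too few stable genes to build a panel")
  adj <- ab$expr[stable, , drop = FALSE]

  std <- fit_standardization(adj, config)
  zmat <- apply_standardization(adj, std)

  zw <- welch_z(zmat, ann$subtype)
  scores <- z_variance(zw)
  panel <- greedy_prune(scores, zmat, config$prune_r, config$panel_size)
  say("panel: %d genes", length(panel$genes))

  zpanel <- zmat[panel$genes, , drop = FALSE]
  covariates <- ann[, c("sex", "age_years"), drop = FALSE]

  subtype_panel <- fit_panel(zpanel, ann$subtype, covariates, min_cases = 2L)

  driver_labels <- vapply(ann$lesion_genes, pseudo_subtype_label, "")
  driver_panel <- tryCatch(
    fit_panel(zpanel, driver_labels, covariates,
              min_cases = config$min_combo_cases),
    error = function(e) {
      warning(sprintf("driver panel not fitted: %s", conditionMessage(e)))
      NULL
    }
  )

  tissue_panel <- NULL
  if (!is.null(tissue_ref)) {
    # the tissue panel is standardized against the reference collection, not
    # the leukemia cohort: relative to its own cohort's center every patient
    # is featureless, whereas relative to the tissue collection the typical
    # B-ALL profile is a strong, recognizable pattern
    ref_genes <- intersect(panel$genes, rownames(tissue_ref$expr))
    if (length(ref_genes) < 2L) stop("tissue reference covers too few panel genes")
    std_t <- fit_standardization(tissue_ref$expr[ref_genes, , drop = FALSE], config)
    zt <- apply_standardization(tissue_ref$expr, std_t)
    tissue_panel <- fit_panel(zt, tissue_ref$labels, covariates = NULL,
                              min_cases = 2L)
    tissue_panel$standardization <- unclass(std_t)
  }

  structure(list(
    version = MODEL_SCHEMA_VERSION,
    panel = list(genes = panel$genes, scores = panel$scores),
    standardization = unclass(restrict_standardization(std, panel$genes)),
    panels = list(subtype = subtype_panel, driver = driver_panel,
                  tissue = tissue_panel),
    thresholds = list(proximity = config$proximity_threshold,
                      exclusivity = config$exclusivity_threshold),
    config = unclass(config),
    training_info = list(
      n_samples = ncol(counts),
      n_genes_input = nrow(counts),
      n_genes_usable = length(usable),
      n_genes_excluded_aligned = nrow(ab$batch_model$excluded_genes),
      n_genes_stable = length(stable),
      n_matched_groups = length(matched$groups)
    )
  ), class = "centroid_model")
}

# Fit one panel (centroids + probit calibration) on standardized expression.
fit_panel <- function(zpanel, labels, covariates, min_cases) {
  centroids <- fit_centroids(zpanel, labels, min_cases = min_cases)
  sims <- suppressWarnings(cor(zpanel, centroids)) # samples x categories
  sims[!is.finite(sims)] <- 0 # zero-variance sample or centroid
  calibration <- fit_probit(sims, labels, covariates)
  list(centroids = centroids, calibration = unclass(calibration))
}

restrict_standardization <- function(std, genes) {
  structure(list(center = std$center[genes], scale = std$scale[genes],
                 winsor_limit = std$winsor_limit),
            class = "standardization_params")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("leukotype centroid model\n")
  cat(sprintf("  panel genes:        %d\n", length(x$panel$genes)))
  cat(sprintf("  subtype categories: %d\n", ncol(x$panels$subtype$centroids)))
  if (!is.null(x$panels$driver)) {
    cat(sprintf("  driver categories:  %d\n", ncol(x$panels$driver$centroids)))
  }
  if (!is.null(x$panels$tissue)) {
    cat(sprintf("  tissue categories:  %d\n", ncol(x$panels$tissue$centroids)))
  }
  cat(sprintf("  thresholds:         proximity >= %.2f, exclusivity >= %.2f\n",
              x$thresholds$proximity, x$thresholds$exclusivity))
  invisible(x)
}
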