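#' Simulation configuration for multi-cohort B-ALL count data
#'
#' Defines the statistical structure the training pipeline assumes and must
#' be able to untangle: several cohorts (batches) whose subtype frequencies
#' differ — so batch is confounded with biology by design — with per-batch
#' and per-library-format additive offsets on the log2 scale, subtype-
#' specific mean shifts on disjoint marker-gene sets, a fraction of samples
#' with undefined genomic subtype (the per-batch frequency remainder),
#' low-tumour-burden samples whose expression drifts toward a whole-blood
#' reference profile, and sex/age covariates. Counts are negative binomial
#' with log-space additive effects, the standard bulk RNA-seq noise model.
#'
#' Defaults describe a two-batch (pediatric/adult) design with six distinct
#' subtypes carrying 30 marker genes each at a 2.0 log2-unit effect,
#' per-gene batch offsets with sd 0.5 and 300 samples per batch.
#'
#' @param n_genes number of genes.
#' @param subtypes data frame with columns `name`, `n_markers`, `effect`
#'   (log2 units) and one frequency column per batch named
#'   `freq_<batch name>`; per-batch frequencies must sum to <= 1, the
#'   remainder being Undefined samples.
#' @param batches data frame with columns `name`, `n`, `offset_sd` (per-gene
#'   batch offset sd, log2 units), `format_sd` (per-gene library-format
#'   offset sd), `frac_stranded`, `age_mean`, `age_sd`.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param baseline_mean,baseline_sd per-gene baseline log2-mean
#'   distribution.
#' @param libsize_sd per-sample log2 library-size sd.
#' @param low_burden_fraction fraction of defined-subtype samples with low
#'   leukemia burden.
#' @param low_burden_lambda mixture weight of the ALL profile for low-burden
#'   samples (`1 - lambda` goes to the whole-blood reference).
#' @param blood_shift_sd sd of the whole-blood reference profile's per-gene
#'   log2 deviation from baseline.
#' @param sex_prob probability of sex `"F"`.
#' @param lesion_map named list mapping each subtype to its lesion gene-set.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L,
                              subtypes = NULL,
                              batches = NULL,
                              dispersion = 0.3,
                              baseline_mean = 5,
                              baseline_sd = 2,
                              libsize_sd = 0.3,
                              low_burden_fraction = 0.05,
                              low_burden_lambda = 0.3,
                              blood_shift_sd = 1.0,
                              sex_prob = 0.5,
                              lesion_map = NULL) {
  if (is.null(batches)) {
    batches <- data.frame(
      name = c("pediatric", "adult"),
      n = c(300L, 300L),
      offset_sd = c(0.5, 0.5),
      format_sd = c(0.25, 0.25),
      frac_stranded = c(0.8, 0.5),
      age_mean = c(7, 45),
      age_sd = c(4, 15),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(subtypes)) {
    subtypes <- data.frame(
      name = c("ETV6_RUNX1", "KMT2A", "DUX4", "PAX5_P80R", "TCF3_PBX1", "ZNF384"),
      n_markers = rep(30L, 6L),
      effect = rep(2.0, 6L),
      stringsAsFactors = FALSE
    )
    # default frequencies flip strongly between alternating batches so that
    # batch is confounded with biology while overall prevalences stay similar
    pat <- list(c(0.22, 0.04, 0.18, 0.06, 0.14, 0.06),
                c(0.04, 0.20, 0.06, 0.16, 0.06, 0.18))
    for (i in seq_len(nrow(batches))) {
      subtypes[[paste0("freq_", batches$name[i])]] <- pat[[(i - 1L) %% 2L + 1L]]
    }
  }
  if (is.null(lesion_map)) {
    lesion_map <- list(
      ETV6_RUNX1 = c("ETV6", "RUNX1"),
      KMT2A = c("KMT2A", "AFF1"),
      DUX4 = c("DUX4", "IGH"),
      PAX5_P80R = c("PAX5"),
      TCF3_PBX1 = c("TCF3", "PBX1"),
      ZNF384 = c("ZNF384", "EP300")
    )
    lesion_map <- lesion_map[intersect(names(lesion_map), subtypes$name)]
  }
  freq_cols <- paste0("freq_", batches$name)
  missing_cols <- setdiff(freq_cols, colnames(subtypes))
  if (length(missing_cols)) {
    stop(sprintf("subtypes must carry frequency column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  for (fc in freq_cols) {
    if (any(subtypes[[fc]] < 0) || sum(subtypes[[fc]]) > 1 + 1e-12) {
      stop(sprintf("%s frequencies must be >= 0 and sum to <= 1", fc))
    }
  }
  if (any(subtypes$effect < 0)) stop("effect sizes must be >= 0")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (sum(subtypes$n_markers) > n_genes) stop("more marker genes than genes")
  structure(list(
    n_genes = as.integer(n_genes), subtypes = subtypes, batches = batches,
    dispersion = dispersion, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, libsize_sd = libsize_sd,
    low_burden_fraction = low_burden_fraction,
    low_burden_lambda = low_burden_lambda,
    blood_shift_sd = blood_shift_sd, sex_prob = sex_prob,
    lesion_map = lesion_map
  ), class = "simulation_config")
}

# Gene-level parameters shared between the cohort and the tissue-reference
# simulators: deterministic given (config, seed), so both views of the same
# synthetic world agree on baselines, marker assignments and the blood
# profile.
sim_gene_params <- function(config, seed) {
  local_seed(seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    baseline <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
    names(baseline) <- genes
    marker_pool <- sample(genes, sum(config$subtypes$n_markers))
    markers <- split(marker_pool,
                     rep(config$subtypes$name, config$subtypes$n_markers))
    effects <- matrix(0, nrow = config$n_genes, ncol = nrow(config$subtypes),
                      dimnames = list(genes, config$subtypes$name))
    for (k in config$subtypes$name) {
      eff <- config$subtypes$effect[config$subtypes$name == k]
      n_mk <- length(markers[[k]])
      # real signatures are long-tailed: a few strong hub genes (think DUX4)
      # plus many moderate responders; Gamma(2) magnitudes, mean preserved
      effects[markers[[k]], k] <- eff * rgamma(n_mk, shape = 2, rate = 2)
    }
    blood <- baseline + rnorm(config$n_genes, 0, config$blood_shift_sd)
    list(genes = genes, baseline = baseline, markers = markers,
         effects = effects, blood = blood)
  })
}

#' Simulate a multi-cohort B-ALL count dataset
#'
#' Draws per-sample subtype labels from the per-batch frequencies (the
#' remainder is Undefined), builds log2-scale means as
#' `baseline + subtype effect + batch offset + library-format offset +
#' library size`, blends low-burden samples toward the whole-blood reference
#' profile at the count-mean level, and samples negative-binomial counts.
#' Fully deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `counts` (integer matrix), `annotations` (data frame as
#'   in [read_annotations()]) and `truth` (marker gene sets, per-batch and
#'   per-format offsets, the blood profile, low-burden sample IDs and
#'   mixture weight).
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  gp <- sim_gene_params(config, seed)
  local_seed(seed + 1L, {
    bt <- config$batches
    st <- config$subtypes
    n_total <- sum(bt$n)
    sample_ids <- sprintf("S%04d", seq_len(n_total))

    batch <- rep(bt$name, bt$n)
    subtype <- character(n_total)
    for (b in bt$name) {
      freqs <- st[[paste0("freq_", b)]]
      idx <- which(batch == b)
      subtype[idx] <- sample(c(st$name, "Undefined"), length(idx),
                             replace = TRUE, prob = c(freqs, 1 - sum(freqs)))
    }

    batch_offsets <- sapply(seq_len(nrow(bt)), function(i) {
      rnorm(config$n_genes, 0, bt$offset_sd[i])
    })
    dimnames(batch_offsets) <- list(gp$genes, bt$name)
    formats <- c("stranded", "unstranded")
    format_offsets <- sapply(formats, function(f) rnorm(config$n_genes, 0, 1))
    # scale per batch below; store the unit-variance directions
    dimnames(format_offsets) <- list(gp$genes, formats)

    library_format <- character(n_total)
    for (i in seq_len(nrow(bt))) {
      idx <- which(batch == bt$name[i])
      library_format[idx] <- ifelse(runif(length(idx)) < bt$frac_stranded[i],
                                    "stranded", "unstranded")
    }

    libsize <- rnorm(n_total, 0, config$libsize_sd)
    sex <- ifelse(runif(n_total) < config$sex_prob, "F", "M")
    age <- numeric(n_total)
    for (i in seq_len(nrow(bt))) {
      idx <- which(batch == bt$name[i])
      age[idx] <- pmax(0, rnorm(length(idx), bt$age_mean[i], bt$age_sd[i]))
    }

    defined <- subtype != "Undefined"
    low_burden <- rep(FALSE, n_total)
    n_lb <- round(config$low_burden_fraction * sum(defined))
    if (n_lb > 0) low_burden[sample(which(defined), n_lb)] <- TRUE

    counts <- matrix(0L, nrow = config$n_genes, ncol = n_total,
                     dimnames = list(gp$genes, sample_ids))
    size <- 1 / config$dispersion
    for (j in seq_len(n_total)) {
      bio <- gp$baseline
      if (defined[j]) bio <- bio + gp$effects[, subtype[j]]
      bi <- match(batch[j], bt$name)
      tech <- batch_offsets[, batch[j]] +
        bt$format_sd[bi] * format_offsets[, library_format[j]] +
        libsize[j]
      mu <- 2^(bio + tech)
      if (low_burden[j]) {
        lam <- config$low_burden_lambda
        mu <- 2^tech * (lam * 2^bio + (1 - lam) * 2^gp$blood)
      }
      counts[, j] <- rnbinom(config$n_genes, mu = mu, size = size)
    }

    lesions <- lapply(seq_len(n_total), function(j) {
      if (!defined[j]) return(character(0))
      config$lesion_map[[subtype[j]]] %||% character(0)
    })

    annotations <- data.frame(
      sample_id = sample_ids,
      cohort = batch,
      batch = batch,
      subtype = subtype,
      lesion_genes = I(lesions),
      sex = sex,
      age_years = round(age, 1),
      library_format = library_format,
      stringsAsFactors = FALSE
    )
    truth <- list(
      markers = gp$markers,
      batch_offsets = batch_offsets,
      format_offsets = format_offsets,
      blood_profile = gp$blood,
      baseline = gp$baseline,
      low_burden = sample_ids[low_burden],
      low_burden_lambda = config$low_burden_lambda
    )
    list(counts = counts, annotations = annotations, truth = truth)
  })
}

#' Simulate tissue reference expression profiles
#'
#' Reference log2-expression profiles for the tissue panel: each tissue
#' group has a distinct mean profile with within-group noise. The `B_ALL`
#' group is built from patient-like profiles — the leukemia baseline plus
#' one randomly drawn subtype signature per reference sample — and the
#' `whole_blood` group sits at the same whole-blood profile used for
#' low-burden blending in [simulate_cohort()], so that a low-burden sample
#' genuinely drifts toward the blood reference. Deterministic given (config, seed): use the same
#' pair as the cohort simulation to stay in the same synthetic world.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (match the cohort's).
#' @param tissues tissue group names; must include at least 2 groups.
#'   `B_ALL` and `whole_blood` have the fixed meanings above; any other name
#'   gets an independent random profile.
#' @param n_per_tissue reference samples per group.
#' @param noise_sd within-group log2 noise sd; 0 gives exact group means.
#' @return list with `expr` (log2 expression matrix, genes x reference
#'   samples) and `labels` (tissue group per reference sample).
#' @export
simulate_tissue_reference <- function(config, seed = 1L,
                                      tissues = c("B_ALL", "whole_blood",
                                                  "bone_marrow", "spleen"),
                                      n_per_tissue = 30L,
                                      noise_sd = 0.3) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(tissues) < 2L) stop("need at least 2 tissue groups")
  gp <- sim_gene_params(config, seed)
  local_seed(seed + 2L, {
    profiles <- sapply(tissues, function(tt) {
      if (tt == "B_ALL") return(gp$baseline)
      if (tt == "whole_blood") return(gp$blood)
      gp$baseline + rnorm(config$n_genes, 0, 1)
    })
    dimnames(profiles) <- list(gp$genes, tissues)
    labels <- rep(tissues, each = n_per_tissue)
    ids <- sprintf("REF_%s_%02d", labels, sequence(rep(n_per_tissue, length(tissues))))
    expr <- profiles[, labels, drop = FALSE] +
      matrix(rnorm(config$n_genes * length(labels), 0, noise_sd),
             nrow = config$n_genes)
    dimnames(expr) <- list(gp$genes, ids)
    # the leukemia reference group is built from patient-like profiles, so
    # each B_ALL reference sample carries one subtype's expression signature
    ball <- which(labels == "B_ALL")
    if (length(ball)) {
      drawn <- sample(colnames(gp$effects), length(ball), replace = TRUE)
      expr[, ball] <- expr[, ball] + gp$effects[, drawn]
    }
    list(expr = expr, labels = labels, profiles = profiles)
  })
}

#' Write a simulated cohort to disk
#'
#' Emits `<prefix>_counts.tsv`, `<prefix>_meta.tsv`, `<prefix>_truth.tsv`
#' (per-sample ground truth) and `<prefix>_markers.tsv` (gene, subtype).
#'
#' @param sim result of [simulate_cohort()].
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(
    counts = paste0(prefix, "_counts.tsv"),
    meta = paste0(prefix, "_meta.tsv"),
    truth = paste0(prefix, "_truth.tsv"),
    markers = paste0(prefix, "_markers.tsv")
  )
  write_counts(sim$counts, paths["counts"])
  write_annotations(sim$annotations, paths["meta"])
  truth_tab <- data.frame(
    sample_id = sim$annotations$sample_id,
    true_subtype = sim$annotations$subtype,
    low_burden = sim$annotations$sample_id %in% sim$truth$low_burden,
    stringsAsFactors = FALSE
  )
  write.table(truth_tab, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  markers_tab <- data.frame(
    gene = unlist(sim$truth$markers, use.names = FALSE),
    subtype = rep(names(sim$truth$markers), lengths(sim$truth$markers)),
    stringsAsFactors = FALSE
  )
  write.table(markers_tab, paths["markers"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
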