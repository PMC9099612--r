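# Shared fixtures, built in code. The trained model is expensive enough to
# share across test files; it is memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

# Canonical synthetic world: default study conditions, seed 1.
fixture_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_cohort(simulation_config(), seed = 1L)
  }
  .fixture_cache$sim
}

# Model trained on the canonical world (with driver and tissue panels),
# plus its train/test split.
fixture_model <- function() {
  if (is.null(.fixture_cache$model)) {
    sim <- fixture_sim()
    split <- stratified_split(sim$annotations, fraction = 0.6, seed = 1L)
    tref <- simulate_tissue_reference(simulation_config(), seed = 1L)
    model <- suppressWarnings(train_classifier(
      sim$counts[, split$train],
      sim$annotations[sim$annotations$sample_id %in% split$train, ],
      pipeline_config(),
      val_counts = sim$counts[, split$test],
      tissue_ref = tref
    ))
    .fixture_cache$model <- list(model = model, split = split, tissue_ref = tref)
  }
  .fixture_cache$model
}

# Small deterministic count matrix with valid IDs.
tiny_counts <- function(n_genes = 6L, n_samples = 4L, seed = 99L) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = 50), nrow = n_genes,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

# Minimal annotation table for hand-built scenarios.
tiny_annotations <- function(sample_ids, batch = "b1", subtype = "A",
                             lesions = NULL) {
  n <- length(sample_ids)
  data.frame(
    sample_id = sample_ids,
    cohort = rep_len(batch, n),
    batch = rep_len(batch, n),
    subtype = rep_len(subtype, n),
    lesion_genes = I(lesions %||% replicate(n, character(0), simplify = FALSE)),
    sex = rep_len("M", n),
    age_years = rep_len(10, n),
    library_format = rep_len("stranded", n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent naive greedy pruning: double loop over sorted candidates,
# recomputing correlations with cor() pair by pair.
naive_greedy <- function(scores, expr, prune_r, panel_size) {
  ord <- names(scores)[order(-scores, names(scores))]
  picked <- character(0)
  for (g in ord) {
    if (sd(expr[g, ]) == 0) next
    ok <- TRUE
    for (h in picked) {
      if (abs(cor(expr[g, ], expr[h, ])) >= prune_r) { ok <- FALSE; break }
    }
    if (ok) picked <- c(picked, g)
    if (length(picked) >= panel_size) break
  }
  picked
}
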