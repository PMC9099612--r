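test_that("surrogate removal strips a planted artifact direction", {
  set.seed(10)
  n_genes <- 60; n <- 40
  ann <- tiny_annotations(sprintf("S%02d", 1:n),
                          subtype = rep(c("A", "B"), each = n / 2))
  v <- rnorm(n)
  # centre the artifact within each subtype group so that it is pure
  # nuisance, orthogonal to the protected biology
  for (g in unique(ann$subtype)) {
    sel <- ann$subtype == g
    v[sel] <- v[sel] - mean(v[sel])
  }
  v <- v / sqrt(sum(v^2))
  loading <- rnorm(n_genes, sd = 3)
  expr <- matrix(rnorm(n_genes * n, sd = 0.2), n_genes, n,
                 dimnames = list(sprintf("G%02d", 1:n_genes), ann$sample_id))
  expr <- expr + loading %*% t(v)
  adj <- remove_surrogates(expr, ann, n_surrogates = 2)
  r <- apply(adj, 1, cor, y = v)
  expect_lt(mean(abs(r)), 0.05)
})

test_that("surrogate removal protects subtype-aligned variation", {
  set.seed(11)
  n_genes <- 40; n <- 30
  grp <- rep(c("A", "B", "C"), each = n / 3)
  ann <- tiny_annotations(sprintf("S%02d", 1:n), subtype = grp)
  # artifact identical to the subtype-A indicator
  ind <- as.numeric(grp == "A")
  expr <- matrix(rnorm(n_genes * n, sd = 0.3), n_genes, n,
                 dimnames = list(sprintf("G%02d", 1:n_genes), ann$sample_id))
  expr <- expr + rnorm(n_genes, sd = 2) %*% t(ind)
  adj <- remove_surrogates(expr, ann, n_surrogates = 3)
  before <- colMeans(t(expr) * ind) * n / sum(ind)
  after <- colMeans(t(adj) * ind) * n / sum(ind)
  # group means live in the protected component and survive
  expect_equal(after, before, tolerance = 0.15)
})

test_that("surrogate removal honours degenerate settings and size limits", {
  expr <- tiny_counts(10L, 8L)
  ann <- tiny_annotations(colnames(expr))
  expect_equal(remove_surrogates(expr, ann, 0), expr, ignore_attr = TRUE)
  expect_error(remove_surrogates(expr, ann, 7), "n_surrogates \\+ 2")
})

test_that("matched subsets group pseudo-subtypes across batches", {
  ann <- tiny_annotations(
    sprintf("S%d", 1:6),
    batch = c("b1", "b1", "b2", "b2", "b1", "b2"),
    subtype = c("Ph", "Ph", "Ph", "X", "Y", "Z"),
    lesions = list(c("BCR", "ABL1"), c("ABL1", "BCR"), c("BCR", "ABL1"),
                   character(0), character(0), character(0))
  )
  ms <- match_subsets(ann)
  expect_named(ms$groups, "ABL1,BCR")
  expect_setequal(unlist(ms$groups[["ABL1,BCR"]]), c("S1", "S2", "S3"))
  # lesion-free samples match on subtype; X/Y/Z appear in one batch only
  expect_setequal(ms$unmatched, c("S4", "S5", "S6"))
})

test_that("batch alignment recovers a constant shift and is idempotent", {
  set.seed(12)
  n_genes <- 30; n <- 40
  batch <- rep(c("b1", "b2"), each = n / 2)
  subtype <- rep(rep(c("A", "B"), each = n / 4), 2)
  ann <- tiny_annotations(sprintf("S%02d", 1:n), batch = batch, subtype = subtype)
  # deterministic subtype profiles, identical in both batches, so the only
  # batch difference is the planted shift and recovery must be exact
  base <- matrix(rnorm(n_genes * 2), n_genes, 2,
                 dimnames = list(sprintf("G%02d", 1:n_genes), c("A", "B")))
  expr <- base[, subtype]
  colnames(expr) <- ann$sample_id
  delta <- rnorm(n_genes, sd = 1)
  expr[, batch == "b2"] <- expr[, batch == "b2"] + delta

  ms <- match_subsets(ann)
  ab <- align_batches(expr, ms, ann)
  # per-gene batch-mean difference vanishes
  diff_after <- rowMeans(ab$expr[, batch == "b2"]) - rowMeans(ab$expr[, batch == "b1"])
  expect_equal(unname(diff_after), rep(0, n_genes), tolerance = 1e-8)
  # offset difference recovers the planted shift
  est <- ab$batch_model$offsets["b2", ] - ab$batch_model$offsets["b1", ]
  expect_equal(unname(est), unname(delta), tolerance = 1e-8)
  # idempotent: re-aligning the adjusted data changes nothing
  ab2 <- align_batches(ab$expr, ms, ann)
  expect_equal(ab2$expr, ab$expr, tolerance = 1e-8)
  expect_lt(max(abs(ab2$batch_model$offsets)), 1e-8)
  # grand-mean preservation: matched-count-weighted offsets sum to ~0
  w <- ab$batch_model$matched_sample_counts[rownames(ab$batch_model$offsets)]
  expect_lt(max(abs(colSums(ab$batch_model$offsets * w) / sum(w))), 1e-8)
})

test_that("genes aligned perfectly with batch are excluded", {
  expr <- tiny_counts(6L, 8L)
  batch <- rep(c("b1", "b2"), each = 4)
  ann <- tiny_annotations(colnames(expr), batch = batch,
                          subtype = rep(c("A", "B"), 4))
  expr["G01", ] <- c(1, 1, 1, 1, 5, 5, 5, 5)   # constant within, differs between
  expr["G02", ] <- c(rnorm(4), 0, 0, 0, 0)     # expressed in one batch only
  ms <- match_subsets(ann)
  ab <- align_batches(expr, ms, ann)
  expect_setequal(ab$batch_model$excluded_genes$gene, c("G01", "G02"))
  expect_false(any(c("G01", "G02") %in% rownames(ab$expr)))
})

test_that("alignment degrades to a warning no-op without matched groups", {
  expr <- tiny_counts(5L, 6L)
  ann <- tiny_annotations(colnames(expr), batch = rep(c("b1", "b2"), each = 3),
                          subtype = c("A", "A", "A", "B", "B", "B"))
  ms <- match_subsets(ann)
  expect_length(ms$groups, 0)
  expect_warning(ab <- align_batches(expr, ms, ann), "no-op")
  expect_equal(unname(ab$expr), unname(expr))
  expect_true(all(ab$batch_model$offsets == 0))
})

test_that("stability filter keeps faithful genes and drops scrambled ones", {
  set.seed(13)
  n <- 50
  unadj <- matrix(rnorm(5 * n), 5, n,
                  dimnames = list(paste0("G", 1:5), paste0("S", 1:n)))
  adj <- unadj
  adj["G2", ] <- unadj["G2", sample(n)]  # independent permutation: R ~ 0
  adj["G3", ] <- 7                        # constant after adjustment
  kept <- stability_filter(adj, unadj, stability_r = 0.9)
  expect_true(all(c("G1", "G4", "G5") %in% kept))
  expect_false("G2" %in% kept)
  expect_false("G3" %in% kept)
  expect_error(stability_filter(adj[, 1:10], unadj, 0.9), "identical")
})

test_that("adjustment diagnostics tabulate per-level correlations", {
  sim <- fixture_sim()
  expr <- normalize_log2(sim$counts[1:50, ], rep(1, ncol(sim$counts)))
  d <- adjustment_diagnostics(expr, expr, sim$annotations$batch)
  expect_setequal(unique(d$level), unique(sim$annotations$batch))
  expect_equal(d$r_before, d$r_after)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_adjustment_diagnostics(d, path)
  expect_true(file.exists(path))
})
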