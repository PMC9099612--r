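test_that("cohort simulation is deterministic and leaves the caller's RNG alone", {
  cfg <- simulation_config(n_genes = 200L,
    batches = data.frame(name = c("b1", "b2"), n = c(40L, 40L), offset_sd = 0.5,
                         format_sd = 0.25, frac_stranded = 0.5,
                         age_mean = c(7, 45), age_sd = c(4, 15)))
  set.seed(123)
  before <- rnorm(1)
  set.seed(123); rnorm(1)
  s1 <- simulate_cohort(cfg, seed = 5)
  s2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$annotations, s2$annotations)
  after <- rnorm(1)
  set.seed(123); rnorm(1)
  expect_identical(after, rnorm(1)) # global RNG stream unaffected
  s3 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("simulated cohorts carry the advertised structure", {
  sim <- fixture_sim()
  cfg <- simulation_config()
  expect_silent(validate_counts(sim$counts))
  expect_equal(ncol(sim$counts), sum(cfg$batches$n))
  ann <- sim$annotations
  expect_setequal(unique(ann$batch), cfg$batches$name)
  expect_true(all(ann$subtype %in% c(cfg$subtypes$name, "Undefined")))
  # subtype frequencies differ between batches: confounding by design
  tab <- table(ann$batch, ann$subtype)[, cfg$subtypes$name]
  freq <- tab / rowSums(table(ann$batch, ann$subtype))
  expect_gt(max(abs(freq["pediatric", ] - freq["adult", ])), 0.05)
  # lesions come from the configured map; Undefined samples carry none
  und <- ann$subtype == "Undefined"
  expect_true(all(lengths(ann$lesion_genes[und]) == 0))
  def <- which(!und)[1:20]
  for (i in def) {
    expect_setequal(ann$lesion_genes[[i]], cfg$lesion_map[[ann$subtype[i]]])
  }
  expect_true(all(ann$age_years >= 0))
  expect_true(all(ann$sex %in% c("M", "F")))
  # low-burden samples exist, are defined and are listed in the truth
  expect_gt(length(sim$truth$low_burden), 0)
  lb_sub <- ann$subtype[match(sim$truth$low_burden, ann$sample_id)]
  expect_true(all(lb_sub != "Undefined"))
  expect_setequal(names(sim$truth$markers), cfg$subtypes$name)
  expect_true(all(lengths(sim$truth$markers) == cfg$subtypes$n_markers))
})

test_that("marker ranking recovers the signal and the panel spans every subtype", {
  sim <- fixture_sim()
  fx <- fixture_model()
  markers <- sim$truth$markers
  all_markers <- unlist(markers)
  # ranking-level recovery: the top-45 genes by Welch-Z variance are markers
  cfg <- pipeline_config()
  usable <- filter_usable_genes(sim$counts, sim$counts, cfg)
  expr <- normalize_log2(sim$counts[usable, ], size_factors(sim$counts[usable, ]))
  ann <- sim$annotations
  sv <- remove_surrogates(expr, ann, cfg$n_surrogates)
  ab <- align_batches(sv, match_subsets(ann), ann)
  stable <- stability_filter(ab$expr, expr[rownames(ab$expr), ], cfg$stability_r)
  z <- apply_standardization(ab$expr[stable, ], fit_standardization(ab$expr[stable, ], cfg))
  scores <- z_variance(welch_z(z, ann$subtype))
  top45 <- names(sort(scores, decreasing = TRUE))[1:45]
  expect_gte(mean(top45 %in% all_markers), 0.8)
  # every subtype contributes at least one marker to the pruned panel
  per_subtype <- vapply(markers, function(g) sum(fx$model$panel$genes %in% g), 0L)
  expect_true(all(per_subtype >= 1))
})

test_that("tissue references share the synthetic world and support blending", {
  cfg <- simulation_config(n_genes = 300L)
  ref0 <- simulate_tissue_reference(cfg, seed = 5, tissues = c("B_ALL", "whole_blood"),
                                    n_per_tissue = 4L, noise_sd = 0)
  # zero noise: group members equal the configured profiles exactly
  expect_equal(unname(ref0$expr[, ref0$labels == "whole_blood"][, 1]),
               unname(ref0$profiles[, "whole_blood"]))
  gp_truth <- simulate_cohort(cfg, seed = 5)$truth
  expect_equal(ref0$profiles[, "whole_blood"], gp_truth$blood_profile)
  expect_error(simulate_tissue_reference(cfg, seed = 5, tissues = "B_ALL"),
               "2 tissue groups")
})

test_that("low-burden blending drives tissue calls from blood to leukemia", {
  fx <- fixture_model()
  sim <- fixture_sim()
  truth <- sim$truth
  params <- structure(fx$model$standardization, class = "standardization_params")
  genes <- rownames(sim$counts)
  blend_counts <- function(lambda, subtype) {
    bio <- truth$baseline
    bio[truth$markers[[subtype]]] <- bio[truth$markers[[subtype]]] + 2
    mu <- lambda * 2^bio + (1 - lambda) * 2^truth$blood_profile
    setNames(round(mu), genes)
  }
  pure_blood <- classify(matrix(blend_counts(0, "KMT2A"), ncol = 1,
                                dimnames = list(genes, "lb0")), fx$model)
  expect_equal(pure_blood$tissue_call, "whole_blood")
  pure_all <- classify(matrix(blend_counts(1, "KMT2A"), ncol = 1,
                              dimnames = list(genes, "lb1")), fx$model)
  expect_equal(pure_all$tissue_call, "B_ALL")
})

test_that("simulation files land on disk as TSV", {
  cfg <- simulation_config(n_genes = 300L,
    batches = data.frame(name = c("b1", "b2"), n = c(30L, 30L), offset_sd = 0.5,
                         format_sd = 0.25, frac_stranded = 0.5,
                         age_mean = c(7, 45), age_sd = c(4, 15)))
  sim <- simulate_cohort(cfg, seed = 2)
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- write_simulation(sim, prefix)
  expect_true(all(file.exists(paths)))
  expect_identical(read_counts(paths[["counts"]]), sim$counts)
  back <- read_annotations(paths[["meta"]])
  expect_equal(back$subtype, sim$annotations$subtype)
})
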