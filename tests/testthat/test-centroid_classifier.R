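test_that("pseudo-subtype labels are canonical sorted gene sets", {
  expect_equal(pseudo_subtype_label(c("BCR", "ABL1")), "ABL1,BCR")
  expect_equal(pseudo_subtype_label(c("KMT2A", "MLLT1", "ID2", "IGK")),
               "ID2,IGK,KMT2A,MLLT1")
  expect_equal(pseudo_subtype_label(c("BCR", "BCR", "ABL1")), "ABL1,BCR")
  expect_equal(pseudo_subtype_label(character(0)), "")
})

test_that("centroids are category means with minimum-size dropping", {
  expr <- cbind(S1 = c(1, 2), S2 = c(3, 4), S3 = c(-3, -4),
                S4 = c(9, 9), S5 = c(0, 1))
  rownames(expr) <- c("G1", "G2")
  expect_warning(
    cent <- fit_centroids(expr, c("A", "B", "B", "solo", "Undefined"),
                          min_cases = 2L),
    "solo"
  )
  expect_equal(colnames(cent), "B")
  expect_equal(unname(cent[, "B"]), c(0, 0)) # +v and -v average to zero
  cent1 <- fit_centroids(expr[, 1, drop = FALSE], "A", min_cases = 1L)
  expect_equal(unname(cent1[, "A"]), c(1, 2)) # single profile is its own centroid

  # a driver combination with only 4 cases is dropped at min_cases = 5
  expr5 <- cbind(expr, S6 = c(2, 2), S7 = c(2, 3), S8 = c(1, 1), S9 = c(0, 2))
  expect_warning(
    cent5 <- fit_centroids(expr5, rep(c("A", "B"), c(5, 4)), min_cases = 5L),
    "below 5"
  )
  expect_equal(colnames(cent5), "A")
})

test_that("biomarker similarities are correlations with documented tie handling", {
  cent <- cbind(A = c(2, 0, -1), B = c(0, 1, 2))
  rownames(cent) <- paste0("G", 1:3)
  s <- biomarker_scores(setNames(cent[, "A"], rownames(cent)), cent)
  expect_equal(unname(s["A"]), 1)
  expect_equal(attr(s, "best"), "A")
  s2 <- biomarker_scores(setNames(-cent[, "A"], rownames(cent)), cent)
  expect_equal(unname(s2["A"]), -1)
  # equidistant sample: lexicographically smallest category wins
  cent_sym <- cbind(B = c(1, 0), A = c(0, 1))
  rownames(cent_sym) <- c("G1", "G2")
  s3 <- biomarker_scores(c(G1 = 1, G2 = 1), cent_sym)
  expect_equal(unname(s3["A"]), unname(s3["B"]))
  expect_equal(attr(s3, "best"), "A")
  # zero-variance sample is flagged degenerate
  s4 <- biomarker_scores(c(G1 = 0, G2 = 0, G3 = 0), cent)
  expect_true(attr(s4, "degenerate"))
  expect_true(all(s4 == 0))
})

test_that("probit calibration balances classes and handles separation", {
  set.seed(30)
  n <- 120
  lab <- rep(c("A", "B"), c(40, 80))
  sims <- cbind(A = ifelse(lab == "A", 1, -1) * 2 + rnorm(n, sd = 0.2),
                B = ifelse(lab == "B", 1, -1) * 2 + rnorm(n, sd = 0.2))
  cal <- fit_probit(sims, lab)
  expect_s3_class(cal, "probit_calibration")
  expect_gt(cal$fits$A$coef[["similarity"]], 0)

  # perfectly separating similarity: proximities near 0/1, ridge-bounded
  p_pos <- proximity(c(A = 2, B = -2), cal)
  p_neg <- proximity(c(A = -2, B = 2), cal)
  expect_gt(p_pos[["A"]], 0.95)
  expect_lt(p_neg[["A"]], 0.05)
  expect_true(all(is.finite(unlist(lapply(cal$fits, `[[`, "coef")))))

  # duplicating every negative leaves the fit unchanged (balanced weights)
  dup <- c(which(lab == "A"), which(lab == "B"), which(lab == "B"))
  cal2 <- fit_probit(sims[dup, ], lab[dup])
  expect_equal(cal2$fits$A$coef, cal$fits$A$coef, tolerance = 1e-6)

  # a category with < 2 positives falls back to a rank transform
  lab3 <- c("C", rep(c("A", "B"), c(59, 60)))
  cal3 <- fit_probit(cbind(sims, C = rnorm(n)), lab3)
  expect_true(cal3$fits$C$degenerate)
  p3 <- proximity(c(A = 0, B = 0, C = 99), cal3)
  expect_gt(p3[["C"]], 0.95) # above every training similarity
})

test_that("a zero linear predictor gives proximity one half", {
  cal <- structure(list(
    categories = "A",
    fits = list(A = list(coef = c(intercept = 0, similarity = 1.5),
                         degenerate = FALSE)),
    encoding = list(use_covariates = FALSE),
    prior_counts = list(A = 10L)
  ), class = "probit_calibration")
  expect_equal(unname(proximity(c(A = 0), cal)), 0.5)
  # monotone increasing in similarity when the slope is positive
  p <- sapply(seq(-1, 1, by = 0.25), function(s) proximity(c(A = s), cal)[["A"]])
  expect_true(all(diff(p) > 0))
})

test_that("exclusivity follows the chi-squared(1) conversion", {
  expect_equal(exclusivity(c(A = 0.7, B = 0.7)), 0)
  # independent closed form: chi^2(1) CDF(x) = 2 * Phi(sqrt(x)) - 1
  z <- qnorm(c(0.9, 0.1))
  stat <- (z[1] - z[2])^2 / 2
  expect_equal(stat, 3.285, tolerance = 1e-3)
  expect_equal(exclusivity(c(A = 0.9, B = 0.1)), 2 * pnorm(sqrt(stat)) - 1,
               tolerance = 1e-12)
  expect_equal(exclusivity(c(A = 0.9, B = 0.1)), 0.930, tolerance = 1e-3)
  expect_equal(exclusivity(c(A = 0.8)), 1) # single category, by convention
  # strictly increasing in the squared probit gap
  gaps <- seq(0.5, 0.9, by = 0.1)
  e <- sapply(gaps, function(p) exclusivity(c(A = p, B = 1 - p)))
  expect_true(all(diff(e) > 0))
})

test_that("classification flags follow their definitions on constructed samples", {
  fx <- fixture_model()
  model <- fx$model
  params <- structure(model$standardization, class = "standardization_params")
  cents <- model$panels$subtype$centroids
  k <- colnames(cents)[1]
  # invert standardization so the raw sample lands exactly on the centroid
  z_to_counts <- function(z) {
    expr <- z * params$scale + params$center
    counts <- pmax(round(2^expr - 1), 0)
    counts
  }
  at_centroid <- z_to_counts(cents[, k])
  res <- classify(matrix(at_centroid, ncol = 1,
                         dimnames = list(names(at_centroid), "probe1")), model)
  expect_equal(res$best_category, k)
  expect_equal(res$flag, "OK")

  # pure noise (iid in standardized space): poor proximity to any subtype.
  # A featureless profile can still brush a centroid by chance, so the
  # contract is distributional: the large majority of noise probes abstain.
  set.seed(31)
  noise_probes <- sapply(1:12, function(i) {
    z <- rnorm(length(params$center))
    pmax(round(2^(params$center + z * params$scale) - 1), 0)
  })
  dimnames(noise_probes) <- list(names(params$center), paste0("noise", 1:12))
  resn <- classify(noise_probes, model)
  expect_gte(mean(resn$flag == "Unclassified"), 2 / 3)
  expect_lt(median(apply(attr(resn, "proximities"), 1, max)),
            model$thresholds$proximity)
  expect_match(resn$reason[resn$flag == "Unclassified"][1], "poor proximity")

  # midpoint of two centroids: ambiguous call
  k2 <- colnames(cents)[2]
  mid <- z_to_counts((cents[, k] + cents[, k2]) / 2)
  resm <- classify(matrix(mid, ncol = 1,
                          dimnames = list(names(mid), "probe3")), model)
  expect_equal(resm$flag, "Ambiguous")

  # flag semantics: the three flags partition any batch of samples
  sim <- fixture_sim()
  res_all <- classify(sim$counts[, fx$split$test[1:40]], model, sim$annotations)
  expect_true(all(res_all$flag %in% c("OK", "Ambiguous", "Unclassified")))
  prox <- attr(res_all, "proximities")
  expect_true(all((apply(prox, 1, max) < model$thresholds$proximity) ==
                  (res_all$flag == "Unclassified")))
  amb <- res_all$flag == "Ambiguous"
  expect_true(all(res_all$exclusivity[amb] < model$thresholds$exclusivity))
})

test_that("classification of a sample ignores its companions in the call", {
  fx <- fixture_model()
  sim <- fixture_sim()
  ids <- fx$split$test[1:8]
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "proximities") <- NULL
    rownames(x) <- NULL
    x
  }
  joint <- classify(sim$counts[, ids], fx$model, sim$annotations)
  solo <- do.call(rbind, lapply(ids, function(s) {
    strip(classify(sim$counts[, s, drop = FALSE], fx$model, sim$annotations))
  }))
  expect_equal(strip(joint), solo, tolerance = 0)
})

test_that("samples with most panel genes missing are rejected with a reason", {
  fx <- fixture_model()
  genes <- fx$model$panel$genes[1:10] # 10 of 45 genes present
  x <- setNames(rep(50, 10), genes)
  res <- classify(matrix(x, ncol = 1, dimnames = list(genes, "sparse1")), fx$model)
  expect_equal(res$flag, "Unclassified")
  expect_match(res$reason, "panel genes missing")
  expect_gt(res$missing_gene_fraction, 0.5)
})

test_that("driver and tissue panels are reported alongside the subtype call", {
  fx <- fixture_model()
  sim <- fixture_sim()
  res <- classify(sim$counts[, fx$split$test[1:20]], fx$model, sim$annotations)
  expect_true(all(!is.na(res$driver_call)))
  expect_true(all(!is.na(res$tissue_call)))
  expect_true(all(res$driver_proximity >= 0 & res$driver_proximity <= 1))
  drivers <- colnames(fx$model$panels$driver$centroids)
  expect_true(all(res$driver_call %in% drivers))
  expect_true(all(grepl(",|^[A-Z0-9]+$", drivers))) # canonical combination labels
})
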