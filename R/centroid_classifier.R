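#' Canonical pseudo-subtype label from a lesion profile
#'
#' The label of a sample's set of lesion-harboring gene symbols: unique
#' symbols sorted lexicographically and comma-joined, so an individual with
#' a BCR::ABL1 fusion and no other alteration is labelled `"ABL1,BCR"`. An
#' empty lesion set yields the empty label and the sample takes no part in
#' driver-panel training.
#'
#' @param lesions character vector of gene symbols (possibly empty).
#' @return label string.
#' @export
pseudo_subtype_label <- function(lesions) {
  lesions <- unique(lesions[!is.na(lesions) & nzchar(lesions)])
  if (length(lesions) == 0L) return("")
  paste(sort(lesions), collapse = ",")
}

#' Fit per-category centroids
#'
#' Centroid of category k = mean standardized expression of each panel gene
#' over the category's training samples. Categories below `min_cases`
#' training samples are dropped with a warning (subtype panel minimum 2;
#' driver panel minimum `min_combo_cases`).
#'
#' @param expr standardized expression matrix (panel genes x samples).
#' @param labels category label per sample; `NA`, empty and `"Undefined"`
#'   labels are ignored.
#' @param min_cases minimum training samples per category.
#' @return centroid matrix, panel genes x categories (sorted category
#'   names).
#' @export
fit_centroids <- function(expr, labels, min_cases = 2L) {
  usable <- !is.na(labels) & nzchar(labels) & labels != "Undefined"
  x <- expr[, usable, drop = FALSE]
  lab <- labels[usable]
  sizes <- table(lab)
  drop <- names(sizes)[sizes < min_cases]
  if (length(drop)) {
    warning(sprintf("categories below %d cases dropped: %s", min_cases,
                    paste(head(drop, 10L), collapse = ", ")))
  }
  cats <- sort(setdiff(names(sizes), drop))
  if (length(cats) == 0L) stop("no category reaches the minimum size")
  centroids <- vapply(cats, function(k) {
    rowMeans(x[, lab == k, drop = FALSE])
  }, numeric(nrow(x)))
  centroids <- matrix(centroids, nrow = nrow(x),
                      dimnames = list(rownames(x), cats))
  centroids
}

#' Biomarker similarity of a sample to each centroid
#'
#' Similarity is the Pearson correlation between the sample's standardized
#' panel vector and each centroid over the panel genes: robust to residual
#' scale and offset differences in standardized-but-unadjusted unseen
#' samples. The nearest centroid is the argmax; exact ties resolve to the
#' lexicographically smallest category name. A zero-variance sample vector
#' gets similarity 0 to every centroid and is flagged via the `degenerate`
#' attribute.
#'
#' @param sample named numeric vector of standardized expression; genes
#'   missing from the panel are imputed at 0.
#' @param centroids centroid matrix (panel genes x categories).
#' @return named similarity vector with attributes `best` (nearest
#'   category) and `degenerate`.
#' @export
biomarker_scores <- function(sample, centroids) {
  v <- setNames(rep(0, nrow(centroids)), rownames(centroids))
  present <- intersect(names(sample), rownames(centroids))
  v[present] <- sample[present]
  degenerate <- sd(v) == 0
  if (degenerate) {
    sims <- setNames(rep(0, ncol(centroids)), colnames(centroids))
  } else {
    sims <- apply(centroids, 2L, function(ck) {
      if (sd(ck) == 0) 0 else cor(v, ck)
    })
  }
  best <- names(sims)[order(-sims, names(sims))][1L]
  attr(sims, "best") <- best
  attr(sims, "degenerate") <- degenerate
  sims
}

# Ridge-penalised weighted probit regression by Fisher scoring. X must
# include the intercept column (unpenalised); lambda penalises the
# remaining coefficients, which bounds them under perfect separation.
probit_ridge <- function(X, y, w, lambda = 1e-4, maxit = 200L, tol = 1e-10) {
  beta <- numeric(ncol(X))
  pen <- c(0, rep(lambda, ncol(X) - 1L))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
    d <- dnorm(eta)
    grad <- as.vector(crossprod(X, w * d * (y - p) / (p * (1 - p)))) - pen * beta
    W <- w * d * d / (p * (1 - p))
    H <- crossprod(X, X * W) + diag(pen, ncol(X))
    delta <- tryCatch(solve(H, grad), error = function(e) rep(0, ncol(X)))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  beta
}

#' Fit probit calibration for each category
#'
#' One-vs-rest probit regressions convert raw biomarker similarities into
#' proximities: calibrated probabilities of observing the category in the
#' training population, balanced for group sizes and given the similarity
#' and optional sex/age covariates. Balancing uses per-observation weights
#' inversely proportional to class size, so duplicating a class leaves the
#' fit unchanged. A small ridge penalty keeps coefficients finite under
#' perfect separation. Categories with fewer than 2 positive training
#' samples cannot be calibrated; they fall back to a rank-based transform of
#' similarity and are flagged.
#'
#' @param similarities matrix (training samples x categories) of biomarker
#'   similarities.
#' @param labels true category per training sample.
#' @param covariates optional data frame with `sex` (`"M"`/`"F"`/`NA`) and
#'   `age_years` columns aligned to rows of `similarities`; `NULL` fits on
#'   similarity alone.
#' @param lambda ridge penalty.
#' @return a `probit_calibration` list: per-category coefficients
#'   (`intercept`, `similarity`, and when covariates are used `sex`, `age`),
#'   fallback information, the frozen covariate encoding, and per-category
#'   training prior counts.
#' @export
fit_probit <- function(similarities, labels, covariates = NULL, lambda = 1e-4) {
  cats <- colnames(similarities)
  encoding <- encode_covariates(covariates)
  cov_mat <- encoding$design # n x 0 or n x 2 (sex, age_std)
  fits <- list()
  for (k in cats) {
    y <- as.numeric(labels == k)
    y[is.na(y)] <- 0
    n_pos <- sum(y == 1)
    n_neg <- sum(y == 0)
    if (n_pos < 2L || n_neg < 2L) {
      fits[[k]] <- list(coef = NULL, degenerate = TRUE,
                        train_similarities = sort(similarities[, k]))
      next
    }
    w <- ifelse(y == 1, 1 / (2 * n_pos), 1 / (2 * n_neg))
    X <- cbind(intercept = 1, similarity = similarities[, k], cov_mat)
    beta <- probit_ridge(X, y, w, lambda = lambda)
    degenerate <- !is.finite(beta[2L]) || beta[2L] <= 0
    fits[[k]] <- list(coef = setNames(as.numeric(beta), colnames(X)),
                      degenerate = degenerate,
                      train_similarities = if (degenerate) sort(similarities[, k]) else NULL)
  }
  structure(
    list(categories = cats, fits = fits, encoding = encoding$params,
         prior_counts = as.list(table(factor(labels, levels = cats)))),
    class = "probit_calibration"
  )
}

# Frozen covariate encoding: sex M=0 / F=1 / missing = training mean of the
# observed codes; age standardized by training mean/sd, missing = 0.
encode_covariates <- function(covariates) {
  if (is.null(covariates)) {
    return(list(design = NULL, params = list(use_covariates = FALSE)))
  }
  sex_code <- ifelse(is.na(covariates$sex), NA_real_,
                     ifelse(covariates$sex == "F", 1, 0))
  sex_missing <- if (all(is.na(sex_code))) 0.5 else mean(sex_code, na.rm = TRUE)
  age <- covariates$age_years
  age_mean <- if (all(is.na(age))) 0 else mean(age, na.rm = TRUE)
  age_sd <- if (sum(!is.na(age)) > 1L) sd(age, na.rm = TRUE) else 1
  if (!is.finite(age_sd) || age_sd == 0) age_sd <- 1
  params <- list(use_covariates = TRUE, sex_missing = sex_missing,
                 age_mean = age_mean, age_sd = age_sd)
  list(design = apply_covariate_encoding(covariates, params), params = params)
}

apply_covariate_encoding <- function(covariates, params) {
  if (!isTRUE(params$use_covariates)) return(NULL)
  if (is.null(covariates)) {
    covariates <- data.frame(sex = NA_character_, age_years = NA_real_)
  }
  sex_code <- ifelse(is.na(covariates$sex), params$sex_missing,
                     ifelse(covariates$sex == "F", 1, 0))
  age_std <- ifelse(is.na(covariates$age_years), 0,
                    (covariates$age_years - params$age_mean) / params$age_sd)
  cbind(sex = sex_code, age = age_std)
}

#' Calibrated proximity of a sample to each category
#'
#' `proximity_k = Phi(b0 + b1 * similarity_k + b2 * sex + b3 * age_std)`
#' with the frozen training covariate encoding; missing covariates use the
#' training encodings. Uncalibrated categories (fallback) use the rank of
#' the similarity among the training similarities.
#'
#' @param similarities named per-category similarity vector for one sample.
#' @param calibration a `probit_calibration`.
#' @param covariates optional one-row data frame with `sex` and `age_years`.
#' @return named per-category proximity vector in `[0, 1]`.
#' @export
proximity <- function(similarities, calibration, covariates = NULL) {
  stopifnot(inherits(calibration, "probit_calibration"))
  cov_row <- apply_covariate_encoding(covariates, calibration$encoding)
  out <- setNames(numeric(length(calibration$categories)), calibration$categories)
  for (k in calibration$categories) {
    fit <- calibration$fits[[k]]
    s <- similarities[[k]]
    if (is.null(fit$coef) || fit$degenerate) {
      train <- fit$train_similarities
      out[k] <- (sum(train < s) + 0.5 * sum(train == s) + 0.5) / (length(train) + 1)
    } else {
      eta <- fit$coef[["intercept"]] + fit$coef[["similarity"]] * s
      if (isTRUE(calibration$encoding$use_covariates)) {
        eta <- eta + fit$coef[["sex"]] * cov_row[1L, "sex"] +
          fit$coef[["age"]] * cov_row[1L, "age"]
      }
      out[k] <- pnorm(eta)
    }
  }
  out
}

#' Exclusivity of the best subtype call
#'
#' Measures how uniquely the top category is supported: the best and
#' second-best proximities are mapped to the probit scale, their difference
#' is converted to the statistic `(z_best - z_second)^2 / 2`, and the
#' chi-squared distribution with one degree of freedom turns the statistic
#' into a probability. Zero proximity difference gives exclusivity 0
#' (maximally ambiguous); a single category gives 1 by convention.
#' Proximities are clipped to `[1e-12, 1 - 1e-12]` before the probit map.
#'
#' @param proximities named per-category proximity vector.
#' @return exclusivity probability in `[0, 1]`.
#' @export
exclusivity <- function(proximities) {
  if (length(proximities) < 2L) return(1)
  p <- sort(unname(proximities), decreasing = TRUE)[1:2]
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  z <- qnorm(p)
  stat <- (z[1L] - z[2L])^2 / 2
  pchisq(stat, df = 1L)
}

#' Classify samples with a fitted centroid model
#'
#' The full single-sample pipeline: raw counts are normalized with a unit
#' size factor (a lone sample has no cohort to share a reference with),
#' log2-transformed, standardized with the frozen training parameters,
#' correlated against the subtype centroids, calibrated into proximities
#' and summarized with an exclusivity score and a quality flag. Driver-gene
#' and tissue panels, when present in the model, are evaluated with the
#' same machinery on their own centroid sets. Each sample is processed
#' independently: results never depend on which other samples are in the
#' same call.
#'
#' The predicted subtype is the nearest centroid (largest biomarker
#' similarity); calibrated proximities quality-gate the call. Flags:
#' `Unclassified` when no category reaches the model's proximity threshold
#' (or more than half the panel genes are missing); `Ambiguous` when
#' classifiable but exclusivity is below the exclusivity threshold; `OK`
#' otherwise.
#'
#' @param counts count matrix (genes x samples), a named count vector for
#'   one sample, or an expression matrix when `input = "expression"`.
#' @param model a `centroid_model` from [train_classifier()].
#' @param annotations optional annotation data frame supplying sex/age
#'   covariates for the samples.
#' @param input `"counts"` (default: normalize + log2 first) or
#'   `"expression"` (already on the log2 scale).
#' @return a `classification_result` data frame, one row per sample, with
#'   columns `sample_id`, `best_category`, `proximity`, `exclusivity`,
#'   `frequency_estimate`, `flag`, `reason`, `driver_call`,
#'   `driver_proximity`, `tissue_call`, `tissue_proximity`,
#'   `missing_gene_fraction`; per-subtype proximities are attached as the
#'   `proximities` attribute (samples x categories).
#' @export
classify <- function(counts, model, annotations = NULL,
                     input = c("counts", "expression")) {
  stopifnot(inherits(model, "centroid_model"))
  input <- match.arg(input)
  if (is.null(dim(counts))) {
    counts <- matrix(counts, ncol = 1L, dimnames = list(names(counts), "sample_1"))
  }
  params <- structure(model$standardization, class = "standardization_params")
  rows <- vector("list", ncol(counts))
  prox_rows <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    sid <- colnames(counts)[j]
    x <- counts[, j]
    names(x) <- rownames(counts)
    expr <- if (input == "counts") log2(x + 1) else x # unit size factor for a lone sample
    z <- apply_standardization(expr, params)
    zvec <- setNames(z[, 1L], rownames(z))
    missing_frac <- unname(attr(z, "missing_fraction")[1L])
    cov <- NULL
    if (!is.null(annotations)) {
      hit <- match(sid, annotations$sample_id)
      if (!is.na(hit)) cov <- annotations[hit, c("sex", "age_years"), drop = FALSE]
    }

    sub <- evaluate_panel(zvec, model$panels$subtype, cov)
    panel_missing <- 1 - mean(model$panel$genes %in% names(x)[!is.na(x)])
    flag <- "OK"
    reason <- ""
    if (panel_missing > 0.5) {
      flag <- "Unclassified"
      reason <- sprintf("more than 50%% of panel genes missing (%.0f%%)",
                        100 * panel_missing)
    } else if (sub$max_proximity < model$thresholds$proximity) {
      flag <- "Unclassified"
      reason <- "poor proximity to any subtype"
    } else if (sub$exclusivity < model$thresholds$exclusivity) {
      flag <- "Ambiguous"
      reason <- sprintf("mixed characteristics: %s vs %s", sub$best, sub$second)
    }

    drv <- if (!is.null(model$panels$driver)) {
      evaluate_panel(zvec, model$panels$driver, cov)
    }
    tis <- if (!is.null(model$panels$tissue)) {
      evaluate_panel(zvec, model$panels$tissue, NULL, log2expr = expr)
    }

    rows[[j]] <- data.frame(
      sample_id = sid,
      best_category = sub$best,
      proximity = sub$best_proximity,
      exclusivity = sub$exclusivity,
      frequency_estimate = sub$best_proximity,
      flag = flag,
      reason = reason,
      driver_call = if (is.null(drv)) NA_character_ else drv$best,
      driver_proximity = if (is.null(drv)) NA_real_ else drv$best_proximity,
      tissue_call = if (is.null(tis)) NA_character_ else tis$best,
      tissue_proximity = if (is.null(tis)) NA_real_ else tis$best_proximity,
      missing_gene_fraction = panel_missing,
      stringsAsFactors = FALSE
    )
    prox_rows[[j]] <- sub$proximities
  }
  out <- do.call(rbind, rows)
  prox <- do.call(rbind, prox_rows)
  rownames(prox) <- out$sample_id
  attr(out, "proximities") <- prox
  class(out) <- c("classification_result", class(out))
  out
}

# Shared per-panel evaluation: similarities -> proximities -> exclusivity.
# A panel carrying its own frozen standardization (the tissue panel, which
# is anchored to the reference collection) re-standardizes the raw log2
# expression instead of using the cohort-standardized vector.
evaluate_panel <- function(zvec, panel, covariates, log2expr = NULL) {
  if (!is.null(panel$standardization) && !is.null(log2expr)) {
    params <- structure(panel$standardization, class = "standardization_params")
    zp <- apply_standardization(log2expr, params)
    zvec <- setNames(zp[, 1L], rownames(zp))
  }
  sims <- biomarker_scores(zvec, panel$centroids)
  prox <- proximity(sims, structure(panel$calibration, class = "probit_calibration"),
                    covariates)
  if (attr(sims, "degenerate")) prox[] <- 0
  ord <- order(-prox, names(prox))
  excl <- if (attr(sims, "degenerate")) 0 else exclusivity(prox)
  # an exact similarity tie for the top spot means no exclusive support
  top_sims <- sort(sims, decreasing = TRUE)
  if (length(sims) >= 2L && top_sims[1L] == top_sims[2L]) excl <- 0
  best <- attr(sims, "best") # nearest centroid by biomarker similarity
  list(best = best,
       second = setdiff(names(prox)[ord], best)[1L],
       best_proximity = unname(prox[best]),
       max_proximity = unname(prox[ord[1L]]),
       exclusivity = excl,
       similarities = sims,
       proximities = prox)
}
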