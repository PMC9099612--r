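#' Stratified train/test split
#'
#' Randomizes samples into training and test sets separately within each
#' subtype (and within the Undefined group) so that subtype frequencies
#' match between the two sets: within each stratum the samples are permuted
#' by a seeded RNG and the first `round(fraction * n)` go to the training
#' set. A stratum of size one goes to the training set with a warning. The
#' caller's global RNG state is left untouched.
#'
#' @param annotations annotation data frame.
#' @param fraction training fraction, in (0, 1).
#' @param seed integer seed; the same seed always yields the same split.
#' @return list with `train` and `test` sample-ID vectors.
#' @export
stratified_split <- function(annotations, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  local_seed(seed, {
    train <- character(0)
    test <- character(0)
    for (k in unique(annotations$subtype)) {
      ids <- annotations$sample_id[annotations$subtype == k]
      if (length(ids) == 1L) {
        warning(sprintf("subtype '%s' has a single sample; assigned to training", k))
        train <- c(train, ids)
        next
      }
      perm <- sample(ids)
      n_train <- round(fraction * length(ids))
      train <- c(train, perm[seq_len(n_train)])
      test <- c(test, perm[-seq_len(n_train)])
    }
    list(train = train, test = test)
  })
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' One-vs-rest confusion metrics with Wilson confidence intervals
#'
#' PPV (the primary metric for low-prevalence subtypes), NPV, sensitivity
#' and specificity for one category, each with a 95% Wilson score interval.
#' Ratios with a zero denominator are reported as `NA` (not available),
#' never as 0.
#'
#' @param predicted,truth aligned label vectors.
#' @param category the positive category.
#' @return one-row data frame with counts, metrics and CI bounds.
#' @export
confusion_metrics <- function(predicted, truth, category) {
  if (length(predicted) != length(truth)) stop("predicted and truth must align")
  pp <- predicted == category
  tp_ <- truth == category
  tp <- sum(pp & tp_); fp <- sum(pp & !tp_)
  fn <- sum(!pp & tp_); tn <- sum(!pp & !tp_)
  metric <- function(x, n) if (n == 0) NA_real_ else x / n
  cis <- rbind(
    ppv = wilson_ci(tp, tp + fp),
    npv = wilson_ci(tn, tn + fn),
    sensitivity = wilson_ci(tp, tp + fn),
    specificity = wilson_ci(tn, tn + fp)
  )
  data.frame(
    category = category, n = length(truth),
    tp = tp, fp = fp, fn = fn, tn = tn,
    ppv = metric(tp, tp + fp), ppv_lo = cis["ppv", 1L], ppv_hi = cis["ppv", 2L],
    npv = metric(tn, tn + fn), npv_lo = cis["npv", 1L], npv_hi = cis["npv", 2L],
    sensitivity = metric(tp, tp + fn),
    sensitivity_lo = cis["sensitivity", 1L], sensitivity_hi = cis["sensitivity", 2L],
    specificity = metric(tn, tn + fp),
    specificity_lo = cis["specificity", 1L], specificity_hi = cis["specificity", 2L],
    stringsAsFactors = FALSE
  )
}

#' Rank-based AUC
#'
#' Area under the ROC curve by the Mann–Whitney statistic with midrank tie
#' handling. `NA` when either class is absent.
#'
#' @param scores numeric scores (larger = more positive).
#' @param truth logical or 0/1 vector of true class membership.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Three-tier quality-gated evaluation
#'
#' Per-category performance at three nested levels of stringency:
#' \describe{
#'   \item{all_samples}{every sample; a sample with undefined genomic
#'     subtype that is predicted into a category counts as a false positive
#'     for that category, making these conservative estimates.}
#'   \item{defined_subtypes}{samples with a confirmed genomic subtype only.}
#'   \item{defined_and_qc_pass}{defined samples whose classification passed
#'     both quality gates (flag `OK`).}
#' }
#'
#' @param results a `classification_result` from [classify()].
#' @param annotations annotation data frame with true `subtype` labels.
#' @param categories categories to evaluate; default: every category
#'   predicted or observed (excluding Undefined).
#' @return data frame of [confusion_metrics()] rows, one per category and
#'   tier, plus AUC per category/tier computed from the per-category
#'   proximities when available.
#' @export
tiered_evaluation <- function(results, annotations, categories = NULL) {
  ann <- annotations[match(results$sample_id, annotations$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotations missing for some classified samples")
  truth <- ann$subtype
  predicted <- results$best_category
  prox <- attr(results, "proximities")
  if (is.null(categories)) {
    categories <- sort(setdiff(union(predicted, truth), "Undefined"))
  }
  tiers <- list(
    all_samples = rep(TRUE, nrow(results)),
    defined_subtypes = truth != "Undefined",
    defined_and_qc_pass = truth != "Undefined" & results$flag == "OK"
  )
  out <- list()
  for (tier in names(tiers)) {
    keep <- tiers[[tier]]
    for (k in categories) {
      row <- confusion_metrics(predicted[keep], truth[keep], k)
      row$auc <- if (!is.null(prox) && k %in% colnames(prox)) {
        auc(prox[keep, k], truth[keep] == k)
      } else NA_real_
      row$tier <- tier
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Write a tiered performance report
#'
#' Emits the [tiered_evaluation()] table as TSV and, optionally, a
#' human-readable text summary.
#'
#' @param report data frame from [tiered_evaluation()].
#' @param path output TSV path.
#' @param text_path optional path for the plain-text summary.
#' @return `path`, invisibly.
#' @export
write_performance_report <- function(report, path, text_path = NULL) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(text_path)) {
    lines <- c("Tiered classification performance", "")
    for (tier in unique(report$tier)) {
      sub <- report[report$tier == tier, ]
      lines <- c(lines, sprintf("== %s (n = %d) ==", tier, sub$n[1L]))
      lines <- c(lines, sprintf(
        "  %-24s PPV %s  [%s, %s]  sens %s",
        sub$category,
        fmt_pct(sub$ppv), fmt_pct(sub$ppv_lo), fmt_pct(sub$ppv_hi),
        fmt_pct(sub$sensitivity)
      ), "")
    }
    writeLines(lines, text_path)
  }
  invisible(path)
}

fmt_pct <- function(x) ifelse(is.na(x), "  n/a", sprintf("%5.1f%%", 100 * x))
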