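#' Remove within-batch surrogate variation
#'
#' Within each batch independently: subtype-group means are subtracted
#' (protecting labelled biology), the top `n_surrogates` principal
#' directions of the residual matrix are extracted, every gene is regressed
#' on them and the fitted nuisance component is removed, after which the
#' group means are restored. The procedure is deterministic and seed-free.
#' Nuisance variation that coincides exactly with a subtype indicator lives
#' in the protected group means and is intentionally preserved.
#'
#' @param expr expression matrix (genes x samples).
#' @param annotations annotation data frame covering the samples; `batch`
#'   and `subtype` are used (samples labelled `"Undefined"` form their own
#'   protected group).
#' @param n_surrogates number of principal residual directions removed per
#'   batch; 0 is the identity transform.
#' @return adjusted expression matrix; the per-batch orthonormal surrogate
#'   directions (samples x directions) are attached as attribute
#'   `surrogates`.
#' @export
remove_surrogates <- function(expr, annotations, n_surrogates) {
  ann <- annotations[match(colnames(expr), annotations$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotations missing for some expression samples")
  n_surrogates <- as.integer(n_surrogates)
  if (n_surrogates == 0L) {
    attr(expr, "surrogates") <- list()
    return(expr)
  }
  out <- expr
  surr <- list()
  for (b in unique(ann$batch)) {
    idx <- which(ann$batch == b)
    if (length(idx) < n_surrogates + 2L) {
      stop(sprintf("batch '%s' has %d samples; need at least n_surrogates + 2 = %d",
                   b, length(idx), n_surrogates + 2L))
    }
    x <- expr[, idx, drop = FALSE]
    grp <- ann$subtype[idx]
    resid <- x
    for (g in unique(grp)) {
      cols <- grp == g
      resid[, cols] <- x[, cols, drop = FALSE] - rowMeans(x[, cols, drop = FALSE])
    }
    k <- min(n_surrogates, length(idx) - 1L, nrow(x))
    sv <- svd(resid, nu = 0L, nv = k)
    v <- sv$v[, seq_len(k), drop = FALSE] # orthonormal in sample space
    rownames(v) <- colnames(x)
    # removing the projection of the residuals onto the surrogate directions
    # is exactly the per-gene regression on the orthonormal directions
    out[, idx] <- x - (resid %*% v) %*% t(v)
    surr[[b]] <- v
  }
  attr(out, "surrogates") <- surr
  out
}

#' Genetically matched subsets across batches
#'
#' Groups samples by their pseudo-subtype label (the canonical sorted,
#' comma-joined set of lesion-harboring gene symbols); samples without
#' recorded lesions are matched on their subtype label instead. Only labels
#' present in at least two batches form matched groups usable for batch
#' alignment.
#'
#' @param annotations annotation data frame.
#' @return list with `groups` (per matched label, a list of per-batch
#'   sample-ID vectors) and `unmatched` (sample IDs in no matched group).
#' @export
match_subsets <- function(annotations) {
  label <- vapply(seq_len(nrow(annotations)), function(i) {
    l <- pseudo_subtype_label(annotations$lesion_genes[[i]])
    if (nzchar(l)) l else annotations$subtype[i]
  }, "")
  groups <- list()
  for (lab in unique(label)) {
    idx <- which(label == lab)
    batches <- annotations$batch[idx]
    if (length(unique(batches)) < 2L) next
    groups[[lab]] <- split(annotations$sample_id[idx], batches)
  }
  matched_ids <- unlist(lapply(groups, unlist), use.names = FALSE)
  list(groups = groups,
       unmatched = setdiff(annotations$sample_id, matched_ids))
}

#' Align batches on genetically matched subsets
#'
#' Estimates one additive offset per (batch, gene) from samples that share a
#' pseudo-subtype across batches, so that technical batch differences are
#' removed while biological differences in subtype composition are not
#' mistaken for batch effects. For each gene, each matched group contributes
#' its per-batch deviation from the group grand mean; per-batch offsets are
#' the group-size-weighted means of those deviations, subtracted from every
#' sample of the batch. The estimate is iterated to convergence
#' (backfitting), which makes the operation idempotent and preserves the
#' grand mean: offsets sum to zero when weighted by matched-sample counts.
#'
#' Genes that are perfectly aligned with batch — constant within every batch
#' yet different between batches, or expressed (nonzero variance) in only
#' one batch — carry no usable biological signal and are excluded.
#'
#' @param expr expression matrix (genes x samples).
#' @param matched result of [match_subsets()].
#' @param batches named character vector mapping sample ID to batch, or an
#'   annotation data frame.
#' @return list with `expr` (adjusted matrix, excluded genes dropped) and
#'   `batch_model` (per-batch per-gene `offsets` matrix and an
#'   `excluded_genes` data frame with columns `gene`, `reason`).
#' @export
align_batches <- function(expr, matched, batches) {
  if (is.data.frame(batches)) {
    batches <- setNames(batches$batch, batches$sample_id)
  }
  batch <- batches[colnames(expr)]
  if (anyNA(batch)) stop("batch labels missing for some expression samples")
  batch_levels <- unique(batch)

  excluded <- perfectly_aligned_genes(expr, batch)
  keep <- setdiff(rownames(expr), excluded$gene)
  x <- expr[keep, , drop = FALSE]

  offsets <- matrix(0, nrow = length(batch_levels), ncol = nrow(x),
                    dimnames = list(batch_levels, rownames(x)))
  groups <- lapply(matched$groups, function(g) {
    ids <- lapply(g, intersect, colnames(x))
    ids[lengths(ids) > 0L]
  })
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  if (length(groups) == 0L) {
    if (length(matched$groups) == 0L) {
      warning("no matched groups span two batches; batch alignment is a no-op")
    }
    return(list(expr = x,
                batch_model = list(offsets = offsets, excluded_genes = excluded)))
  }

  n_matched <- sapply(batch_levels, function(b) {
    sum(vapply(groups, function(g) {
      sum(lengths(g[vapply(g, function(ids) all(batch[ids] == b), TRUE)]))
    }, 0L))
  })

  adj <- x
  for (iter in seq_len(100L)) {
    num <- matrix(0, nrow = length(batch_levels), ncol = nrow(x),
                  dimnames = dimnames(offsets))
    den <- setNames(numeric(length(batch_levels)), batch_levels)
    for (g in groups) {
      ids_all <- unlist(g, use.names = FALSE)
      grand <- rowMeans(adj[, ids_all, drop = FALSE])
      for (ids in g) {
        b <- batch[ids[1L]]
        m <- rowMeans(adj[, ids, drop = FALSE])
        num[b, ] <- num[b, ] + length(ids) * (m - grand)
        den[b] <- den[b] + length(ids)
      }
    }
    step <- num / ifelse(den > 0, den, 1)
    adj <- adj - t(step[batch, , drop = FALSE]) # subtract each sample's batch offset
    offsets <- offsets + step
    if (max(abs(step)) < 1e-10) break
  }
  list(expr = adj,
       batch_model = list(offsets = offsets, excluded_genes = excluded,
                          matched_sample_counts = n_matched))
}

# Identify genes perfectly aligned with batch: constant within every batch
# but differing between batches, or with nonzero variance in only one batch.
perfectly_aligned_genes <- function(expr, batch, tol = 1e-12) {
  batch_levels <- unique(batch)
  vars <- sapply(batch_levels, function(b) row_vars(expr[, batch == b, drop = FALSE]))
  means <- sapply(batch_levels, function(b) rowMeans(expr[, batch == b, drop = FALSE]))
  vars <- matrix(vars, nrow = nrow(expr))
  means <- matrix(means, nrow = nrow(expr))
  vars[is.na(vars)] <- 0
  n_expressed <- rowSums(vars > tol)
  const_within <- rowSums(vars > tol) == 0L
  differs_between <- apply(means, 1L, function(m) max(m) - min(m)) > tol
  flag_const <- const_within & differs_between & length(batch_levels) > 1L
  flag_single <- n_expressed == 1L & length(batch_levels) > 1L
  flagged <- flag_const | flag_single
  data.frame(
    gene = rownames(expr)[flagged],
    reason = rep("perfectly_aligned", sum(flagged)),
    stringsAsFactors = FALSE
  )
}

#' Stability filter: adjusted vs unadjusted expression
#'
#' Keeps genes whose adjusted and unadjusted expression vectors correlate at
#' Pearson `R >= stability_r` across all samples; genes dominated by the
#' confounder adjustment (low correlation) and genes with zero variance in
#' either version (undefined correlation) are excluded as unstable.
#'
#' @param adjusted,unadjusted expression matrices with identical genes and
#'   samples.
#' @param stability_r correlation threshold (default from
#'   [pipeline_config()]: 0.9).
#' @return character vector of stable gene IDs.
#' @export
stability_filter <- function(adjusted, unadjusted,
                             stability_r = pipeline_config()$stability_r) {
  if (!identical(dim(adjusted), dim(unadjusted)) ||
      !identical(rownames(adjusted), rownames(unadjusted)) ||
      !identical(colnames(adjusted), colnames(unadjusted))) {
    stop("adjusted and unadjusted matrices must have identical genes and samples")
  }
  a <- adjusted - rowMeans(adjusted)
  u <- unadjusted - rowMeans(unadjusted)
  num <- rowSums(a * u)
  den <- sqrt(rowSums(a * a) * rowSums(u * u))
  r <- ifelse(den > 0, num / den, NA_real_)
  rownames(adjusted)[!is.na(r) & r >= stability_r]
}

#' Correlation diagnostics for confounder adjustment
#'
#' Per-gene Pearson correlations with the indicator of each level of a
#' grouping variable (batch, library format or subtype), before and after
#' adjustment — the adjustment-quality histograms in tabular form: batch
#' correlations should collapse towards zero while subtype correlations
#' should be preserved.
#'
#' @param before,after expression matrices over the same genes and samples.
#' @param groups character vector of group labels, aligned to columns.
#' @return data frame with columns `gene`, `level`, `r_before`, `r_after`.
#' @export
adjustment_diagnostics <- function(before, after, groups) {
  shared <- intersect(rownames(before), rownames(after))
  out <- list()
  for (lev in unique(groups)) {
    ind <- as.numeric(groups == lev)
    out[[lev]] <- data.frame(
      gene = shared,
      level = lev,
      r_before = row_cor(before[shared, , drop = FALSE], ind),
      r_after = row_cor(after[shared, , drop = FALSE], ind),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write adjustment diagnostics as TSV
#'
#' @param diagnostics data frame from [adjustment_diagnostics()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjustment_diagnostics <- function(diagnostics, path) {
  write.table(diagnostics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
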