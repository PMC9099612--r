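#' Welch Z-scores per gene and subtype
#'
#' For every gene and every subtype, Welch's t-statistic contrasts the
#' subtype's samples against all other labelled samples (one-vs-rest);
#' samples labelled `"Undefined"` are excluded from both groups. The t value
#' is mapped through the cumulative t-distribution at the
#' Welch–Satterthwaite degrees of freedom and the inverse cumulative normal,
#' giving a Z-score per (gene, subtype). Tail probabilities are clipped to
#' `[1e-15, 1 - 1e-15]` so quantiles stay finite.
#'
#' @param expr expression matrix (genes x samples).
#' @param labels subtype label per sample, aligned to columns.
#' @return numeric matrix, genes x subtypes. Subtypes with fewer than 2
#'   samples are skipped with a warning.
#' @export
welch_z <- function(expr, labels) {
  defined <- !is.na(labels) & labels != "Undefined"
  x <- expr[, defined, drop = FALSE]
  lab <- labels[defined]
  subtypes <- sort(unique(lab))
  skipped <- subtypes[table(lab)[subtypes] < 2L]
  if (length(skipped)) {
    warning(sprintf("subtype(s) with < 2 samples skipped: %s",
                    paste(skipped, collapse = ", ")))
    subtypes <- setdiff(subtypes, skipped)
  }
  if (length(subtypes) == 0L) stop("no subtype has >= 2 labelled samples")
  z <- matrix(NA_real_, nrow = nrow(x), ncol = length(subtypes),
              dimnames = list(rownames(x), subtypes))
  for (k in subtypes) {
    in_k <- lab == k
    a <- x[, in_k, drop = FALSE]
    b <- x[, !in_k, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    va <- row_vars(a) / na
    vb <- row_vars(b) / nb
    se2 <- va + vb
    t_stat <- (rowMeans(a) - rowMeans(b)) / sqrt(se2)
    df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    p <- pt(t_stat, df)
    p[se2 == 0] <- 0.5 # both groups constant and equal: no evidence either way
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    z[, k] <- qnorm(p)
  }
  z
}

#' Z-score variance per gene
#'
#' Population variance of each gene's row of Welch Z-scores: the aggregate
#' measure of how strongly a gene segregates between subtypes.
#'
#' @param z matrix from [welch_z()] (genes x subtypes, >= 2 subtypes).
#' @return named non-negative numeric vector, one score per gene.
#' @export
z_variance <- function(z) {
  if (ncol(z) < 2L) stop("z_variance needs >= 2 subtypes")
  m <- rowMeans(z)
  setNames(rowMeans((z - m)^2), rownames(z))
}

#' Greedy decorrelation pruning of a ranked gene list
#'
#' Traverses genes sorted by descending score (ties broken lexicographically
#' by gene ID) and accepts a gene only if its training-data Pearson
#' correlation satisfies `|R| < prune_r` against every already-accepted
#' gene; a correlation at or beyond the threshold blocks the candidate.
#' Selection stops when `panel_size` genes are accepted or the list is
#' exhausted (a short panel triggers a warning). Genes with zero training
#' variance cannot serve as biomarkers and are skipped.
#'
#' @param scores named numeric vector of per-gene scores (e.g.
#'   [z_variance()]).
#' @param expr training expression matrix covering the scored genes. By
#'   contract this is training data only, keeping any validation dataset
#'   untouched by feature selection.
#' @param prune_r correlation threshold.
#' @param panel_size maximum panel size.
#' @return a `gene_panel` list: `genes` (ordered selected IDs), `scores`
#'   (their scores) and `trace` (data frame with one row per visited
#'   candidate: `gene`, `kept`, `blocked_by`).
#' @export
greedy_prune <- function(scores, expr, prune_r = pipeline_config()$prune_r,
                         panel_size = pipeline_config()$panel_size) {
  genes <- intersect(names(scores), rownames(expr))
  if (length(genes) == 0L) stop("scores and expression matrix share no genes")
  scores <- scores[genes]
  ord <- genes[order(-scores, genes)]
  centred <- expr[ord, , drop = FALSE] - rowMeans(expr[ord, , drop = FALSE])
  norms <- sqrt(rowSums(centred^2))
  selected <- character(0)
  trace <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    g <- ord[i]
    if (norms[g] == 0) {
      trace[[i]] <- data.frame(gene = g, kept = FALSE,
                               blocked_by = "zero_variance",
                               stringsAsFactors = FALSE)
      next
    }
    blocker <- NA_character_
    if (length(selected)) {
      r <- as.vector(centred[selected, , drop = FALSE] %*% centred[g, ]) /
        (norms[selected] * norms[g])
      hit <- which(abs(r) >= prune_r)
      if (length(hit)) blocker <- selected[hit[1L]]
    }
    kept <- is.na(blocker)
    if (kept) selected <- c(selected, g)
    trace[[i]] <- data.frame(gene = g, kept = kept, blocked_by = blocker,
                             stringsAsFactors = FALSE)
    if (length(selected) >= panel_size) {
      trace <- trace[seq_len(i)]
      break
    }
  }
  if (length(selected) < panel_size) {
    warning(sprintf("panel has %d genes; requested %d", length(selected), panel_size))
  }
  structure(
    list(genes = selected, scores = scores[selected],
         trace = do.call(rbind, trace)),
    class = "gene_panel"
  )
}

#' Write a gene panel as two-column TSV
#'
#' @param panel a `gene_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.table(data.frame(gene = panel$genes, score = unname(panel$scores)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel written by [write_panel()]
#'
#' @param path panel TSV.
#' @return a `gene_panel` (without selection trace).
#' @export
read_panel <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "score") %in% colnames(tab))) {
    stop("panel file must have columns 'gene' and 'score'")
  }
  structure(list(genes = tab$gene,
                 scores = setNames(tab$score, tab$gene),
                 trace = NULL),
            class = "gene_panel")
}
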