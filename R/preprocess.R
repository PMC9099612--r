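#' Select genes with usable expression
#'
#' A gene is usable as a potential biomarker when its read count reaches
#' `usable_min_count` in at least `ceiling(usable_min_fraction * n)` samples
#' (never fewer than one sample) in *both* the training and the validation
#' count matrices. Only genes present in both matrices are considered.
#'
#' @param train,validation count matrices (genes x samples). When no
#'   separate validation dataset exists, pass the training matrix twice.
#' @param config a [pipeline_config()].
#' @return character vector of usable gene IDs, in training-matrix order.
#' @export
filter_usable_genes <- function(train, validation, config = pipeline_config()) {
  shared <- intersect(rownames(train), rownames(validation))
  if (length(shared) == 0L) stop("train and validation matrices share no genes")
  usable_in <- function(m) {
    thr <- max(1L, ceiling(config$usable_min_fraction * ncol(m)))
    rowSums(m >= config$usable_min_count) >= thr
  }
  ok <- usable_in(train[shared, , drop = FALSE]) &
    usable_in(validation[shared, , drop = FALSE])
  shared[ok]
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors by the median-of-ratios method: the
#' reference profile is the per-gene geometric mean over samples, computed
#' only for genes with no zero count; each sample's factor is the median
#' over reference genes of its count divided by the reference.
#'
#' @param counts count matrix (genes x samples).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  positive <- rowSums(counts == 0) == 0L
  if (!any(positive)) {
    stop("no gene has all-positive counts; prefilter low-expression genes before normalization")
  }
  ref_log <- rowMeans(log(counts[positive, , drop = FALSE]))
  factors <- apply(counts[positive, , drop = FALSE], 2L, function(cnt) {
    exp(median(log(cnt) - ref_log))
  })
  setNames(as.numeric(factors), colnames(counts))
}

#' Depth-normalize and log2-transform counts
#'
#' `value[g, s] = log2(count[g, s] / factor[s] + 1)`.
#'
#' @param counts count matrix.
#' @param factors per-sample positive size factors, aligned to columns.
#' @return numeric expression matrix with the same dimnames.
#' @export
normalize_log2 <- function(counts, factors) {
  if (length(factors) != ncol(counts)) {
    stop("need exactly one size factor per sample")
  }
  if (any(!is.finite(factors) | factors <= 0)) {
    stop("size factors must be positive and finite")
  }
  log2(sweep(counts, 2L, factors, "/") + 1)
}

#' Fit robust standardization parameters
#'
#' Per-gene robust center and scale for the refined Z-score used throughout
#' the classifier: center is the median, scale is the median absolute
#' deviation (scaled by 1.4826 for normal consistency) with fallback to the
#' standard deviation and then to 1 when zero, plus a winsorization bound in
#' standardized units as protection against outliers and skewed
#' distributions. Parameters are frozen at training time and applied
#' unchanged to unseen samples.
#'
#' @param expr expression matrix (genes x samples), at least 3 samples.
#' @param config a [pipeline_config()]; supplies `winsor_limit`.
#' @return a `standardization_params` list with named `center` and `scale`
#'   vectors and the `winsor_limit`.
#' @export
fit_standardization <- function(expr, config = pipeline_config()) {
  if (ncol(expr) < 3L) stop("standardization needs at least 3 samples")
  center <- apply(expr, 1L, median)
  scale <- apply(expr, 1L, mad) # mad() already applies the 1.4826 constant
  fallback <- scale == 0 | !is.finite(scale)
  if (any(fallback)) {
    sds <- apply(expr[fallback, , drop = FALSE], 1L, sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    scale[fallback] <- sds
  }
  structure(
    list(center = center, scale = scale, winsor_limit = config$winsor_limit),
    class = "standardization_params"
  )
}

#' Apply frozen standardization parameters
#'
#' `z = clip((x - center) / scale, -winsor_limit, +winsor_limit)`, gene by
#' gene, sample by sample. Genes covered by the parameters but absent from
#' the input are imputed at the center (standardized 0) and counted; the
#' per-sample missing-gene fraction is attached as the `missing_fraction`
#' attribute for QC. The output for a sample never depends on which other
#' samples are processed in the same call.
#'
#' @param expr expression matrix (genes x samples) or a named vector for a
#'   single sample.
#' @param params a `standardization_params` from [fit_standardization()].
#' @return standardized matrix over the parameter genes (same order), with
#'   attribute `missing_fraction`.
#' @export
apply_standardization <- function(expr, params) {
  stopifnot(inherits(params, "standardization_params"))
  if (is.null(dim(expr))) {
    expr <- matrix(expr, ncol = 1L,
                   dimnames = list(names(expr), "sample"))
  }
  genes <- names(params$center)
  present <- intersect(genes, rownames(expr))
  z <- matrix(0, nrow = length(genes), ncol = ncol(expr),
              dimnames = list(genes, colnames(expr)))
  if (length(present)) {
    z[present, ] <- (expr[present, , drop = FALSE] - params$center[present]) /
      params$scale[present]
  }
  w <- params$winsor_limit
  z <- pmin(pmax(z, -w), w)
  attr(z, "missing_fraction") <-
    setNames(rep(1 - length(present) / length(genes), ncol(z)), colnames(z))
  z
}
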