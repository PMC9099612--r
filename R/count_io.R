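#' Validate a gene-by-sample read-count matrix
#'
#' Checks the contract every downstream stage relies on: an integer-valued,
#' non-negative matrix with unique, non-empty gene row names and sample
#' column names.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @return the validated matrix, invisibly.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (genes x samples)")
  }
  genes <- rownames(counts)
  samples <- colnames(counts)
  if (is.null(genes) || is.null(samples)) {
    stop("counts must carry gene row names and sample column names")
  }
  check_ids(genes, "gene")
  check_ids(samples, "sample")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending cell: gene '%s', sample '%s' (value %s)",
      genes[i[1L]], samples[i[2L]], format(counts[bad[1L]])
    ))
  }
  invisible(counts)
}

check_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("%s IDs must be non-empty strings", what))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s IDs: %s", what, paste(head(dup, 5L), collapse = ", ")))
  }
  invisible(ids)
}

#' Read a gene-by-sample count matrix
#'
#' The canonical interchange format is TSV with a header row of sample IDs,
#' the first column holding gene IDs and tab-separated integer cells.
#' MatrixMarket (`mtx`) input is supported as a convenience; it expects two
#' sidecar files `<path>.genes` and `<path>.samples` holding one ID per line
#' (row and column order of the sparse matrix).
#'
#' @param path path to the count file.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return validated integer matrix with gene row names and sample column
#'   names, in file order.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("count file not found: %s", path))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    gf <- paste0(path, ".genes")
    sf <- paste0(path, ".samples")
    if (!file.exists(gf) || !file.exists(sf)) {
      stop(sprintf("MTX sidecar files missing: expected %s and %s", gf, sf))
    }
    rownames(m) <- readLines(gf)
    colnames(m) <- readLines(sf)
    return(validate_counts(m))
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    stop(sprintf("no header: %s is empty", path))
  }
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("malformed header: need a gene column plus >= 1 sample column")
  genes <- tab[[1L]]
  samples <- colnames(tab)[-1L]
  m <- matrix(NA_real_, nrow = nrow(tab), ncol = length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-integer cell at gene '%s', sample '%s': '%s'",
                   genes[i], samples[j], tab[[j + 1L]][i]))
    }
    m[, j] <- v
  }
  validate_counts(m)
}

#' Write a count matrix as TSV
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  tab <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample annotations
#'
#' Expects a TSV with columns `sample_id`, `cohort`, `batch`, `subtype`,
#' `lesion_genes` (semicolon-separated gene symbols, possibly empty), `sex`
#' (`M`/`F`, empty for missing), `age_years` (empty for missing) and
#' `library_format`. The subtype sentinel for samples without an assigned
#' genomic subtype is the string `"Undefined"`.
#'
#' @param path path to the metadata TSV.
#' @return data frame with one row per sample; `lesion_genes` is a list
#'   column of character vectors, `sex` and `age_years` use `NA` for missing.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  required <- c("sample_id", "cohort", "batch", "subtype", "lesion_genes",
                "sex", "age_years", "library_format")
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols)) {
    stop(sprintf("annotation file missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  check_ids(tab$sample_id, "sample")
  sex <- toupper(trimws(tab$sex))
  sex[!sex %in% c("M", "F")] <- NA_character_
  age <- suppressWarnings(as.numeric(tab$age_years))
  if (any(!is.na(age) & age < 0)) {
    bad <- tab$sample_id[which(!is.na(age) & age < 0)[1L]]
    stop(sprintf("negative age_years for sample '%s'", bad))
  }
  lesions <- lapply(tab$lesion_genes, function(x) {
    parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
    parts <- trimws(parts)
    unique(parts[nzchar(parts)])
  })
  data.frame(
    sample_id = tab$sample_id,
    cohort = tab$cohort,
    batch = tab$batch,
    subtype = tab$subtype,
    lesion_genes = I(lesions),
    sex = sex,
    age_years = age,
    library_format = tab$library_format,
    stringsAsFactors = FALSE
  )
}

#' Write per-sample annotations as TSV
#'
#' Inverse of [read_annotations()]: the `lesion_genes` list column is
#' serialized as semicolon-separated symbols; missing sex/age become empty
#' cells.
#'
#' @param annotations annotation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  tab <- annotations
  tab$lesion_genes <- vapply(annotations$lesion_genes, paste, "", collapse = ";")
  tab$sex[is.na(tab$sex)] <- ""
  tab$age_years <- ifelse(is.na(tab$age_years), "", format(tab$age_years))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Save a fitted centroid model
#'
#' The archive is a single versioned JSON document: human-readable, diffable
#' and auditable. Every numeric field is stored at full double precision so
#' that [load_model()] reproduces the model exactly.
#'
#' @param model a `centroid_model` as returned by [train_classifier()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  doc <- list(schema_version = MODEL_SCHEMA_VERSION,
              model = pack_value(unclass(model)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a centroid model archive
#'
#' @param path path written by [save_model()].
#' @return the restored `centroid_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("cannot parse model archive %s: %s",
                                     path, conditionMessage(e)))
  )
  ver <- doc$schema_version
  if (is.null(ver)) stop("model archive has no schema_version field")
  if (!identical(ver, MODEL_SCHEMA_VERSION)) {
    stop(sprintf("model schema version mismatch: file has '%s', library expects '%s'",
                 ver, MODEL_SCHEMA_VERSION))
  }
  model <- unpack_value(doc$model)
  class(model) <- "centroid_model"
  model
}

# Tagged serialization of the R objects a model contains (NULL, atomic
# vectors with optional names, matrices with dimnames, data frames, lists).
# Explicit tags make the round trip exact and the archive self-describing;
# doubles are written as 17-significant-digit decimal strings, which
# round-trip IEEE doubles bit-exactly while staying human-readable.
pack_value <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.matrix(x)) {
    return(list(t = "matrix", dim = dim(x),
                rownames = rownames(x), colnames = colnames(x),
                data = pack_doubles(as.vector(x))))
  }
  if (is.data.frame(x)) {
    return(list(t = "df", cols = lapply(as.list(x), pack_value)))
  }
  if (is.double(x)) {
    return(list(t = "double", names = names(x), data = pack_doubles(unname(x))))
  }
  if (is.atomic(x)) {
    return(list(t = typeof(x), names = names(x), data = unname(x)))
  }
  if (is.list(x)) {
    return(list(t = "list", names = names(x), data = lapply(x, pack_value)))
  }
  stop(sprintf("cannot serialize object of class %s", paste(class(x), collapse = "/")))
}

pack_doubles <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

unpack_value <- function(x) {
  if (is.null(x$t)) stop("malformed model archive: untagged node")
  t <- x$t
  if (t == "null") return(NULL)
  if (t == "matrix") {
    m <- matrix(vapply(x$data, function(e) {
      if (is.null(e) || identical(e, "NA")) NA_real_ else as.numeric(e)
    }, 0), nrow = x$dim[[1L]], ncol = x$dim[[2L]])
    rownames(m) <- unlist_chr(x$rownames)
    colnames(m) <- unlist_chr(x$colnames)
    return(m)
  }
  if (t == "df") {
    cols <- lapply(x$cols, unpack_value)
    return(data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE))
  }
  if (t == "list") {
    out <- lapply(x$data, unpack_value)
    names(out) <- unlist_chr(x$names)
    return(out)
  }
  # atomic vector tagged with its typeof()
  data <- x$data
  v <- switch(t,
    double = vapply(data, function(e) {
      if (is.null(e) || identical(e, "NA")) NA_real_ else as.numeric(e)
    }, 0),
    integer = vapply(data, function(e) if (is.null(e)) NA_integer_ else as.integer(e), 0L),
    character = vapply(data, function(e) if (is.null(e)) NA_character_ else as.character(e), ""),
    logical = vapply(data, function(e) if (is.null(e)) NA else as.logical(e), TRUE),
    stop(sprintf("unknown type tag '%s' in model archive", t))
  )
  names(v) <- unlist_chr(x$names)
  v
}

unlist_chr <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  vapply(x, as.character, "")
}

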