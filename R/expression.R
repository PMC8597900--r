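#' Expression matrices with a declared scale
#'
#' Throughout the package an expression matrix is a plain numeric matrix with
#' genes in rows and samples in columns, unique `rownames()` (gene ids) and
#' `colnames()` (sample ids), and a `"scale"` attribute declaring the unit of
#' its values: one of `"fpkm"`, `"tpm"`, `"log2tpm"` or `"zscore"`.
#'
#' @param x numeric matrix, genes x samples, with row and column names.
#' @param scale declared scale of the values.
#' @return `x` with the `"scale"` attribute set.
#' @export
expr_matrix <- function(x, scale = c("tpm", "fpkm", "log2tpm", "zscore")) {
  scale <- match.arg(scale)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("`x` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("gene ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("sample ids must be unique", call. = FALSE)
  attr(x, "scale") <- scale
  x
}

#' @rdname expr_matrix
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) NA_character_ else sc
}

check_scale <- function(x, expected, what) {
  sc <- expr_scale(x)
  if (!is.na(sc) && !sc %in% expected) {
    stop(sprintf("%s expects a matrix on the %s scale, got '%s'",
                 what, paste(expected, collapse = "/"), sc), call. = FALSE)
  }
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with gene ids in the first column and sample
#' ids in the header. Gene rows containing any missing value are dropped (with
#' a message giving the count); duplicated gene ids are collapsed by keeping
#' the row with the highest mean expression.
#'
#' @param path path to a TSV file.
#' @param scale declared scale of the stored values.
#' @return an expression matrix (see [expr_matrix()]).
#' @export
read_expression <- function(path, scale = "tpm") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty or malformed expression file: ", path, call. = FALSE)
  }
  gene_ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) & !is.na(vals[[j]]))
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   names(vals)[j], if (length(bad)) bad[1L] else NA_integer_, path),
           call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids

  n_na <- sum(!stats::complete.cases(m))
  if (n_na > 0L) {
    message(n_na, " gene(s) with missing values dropped")
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  if (anyDuplicated(rownames(m))) {
    means <- rowMeans(m)
    ord <- order(-means)          # highest-mean row first, so !duplicated keeps it
    m <- m[ord, , drop = FALSE]
    dup <- duplicated(rownames(m))
    message(sum(dup), " duplicated gene id row(s) collapsed (highest mean kept)")
    m <- m[!dup, , drop = FALSE]
    m <- m[order(match(rownames(m), gene_ids)), , drop = FALSE]
  }
  expr_matrix(m, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' @param x expression matrix.
#' @param path output path.
#' @param gene_col name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, gene_col = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per sample j, `tpm[i, j] = fpkm[i, j] / sum_i(fpkm[i, j]) * 1e6`, so every
#' column of the result sums to one million.
#'
#' @param x expression matrix on the fpkm scale, all values >= 0.
#' @return expression matrix on the tpm scale.
#' @export
fpkm_to_tpm <- function(x) {
  check_scale(x, "fpkm", "fpkm_to_tpm()")
  cs <- colSums(x)
  if (any(cs <= 0)) {
    stop("all-zero expression column(s): ",
         paste(colnames(x)[cs <= 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(x, 2L, cs, "/") * 1e6
  expr_matrix(out, "tpm")
}

#' Log2 transform with unit pseudocount
#'
#' `y = log2(x + 1)`, elementwise. Input values must be non-negative.
#'
#' @param x expression matrix (tpm or fpkm scale).
#' @return expression matrix on the log2tpm scale.
#' @export
log2_transform <- function(x) {
  if (any(x < 0)) stop("negative expression values; log2(x + 1) undefined here",
                       call. = FALSE)
  out <- log2(x + 1)
  expr_matrix(out, "log2tpm")
}

#' Z-score gene rows
#'
#' Centers and scales each gene row to mean 0 and sample standard deviation 1
#' (denominator n - 1). Zero-variance rows are dropped with a message.
#'
#' @param x expression matrix with at least two samples.
#' @return expression matrix on the zscore scale.
#' @export
zscore_rows <- function(x) {
  if (ncol(x) < 2L) stop("z-scoring needs at least 2 samples", call. = FALSE)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) message(sum(!keep), " zero-variance gene row(s) dropped")
  out <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  expr_matrix(out, "zscore")
}

#' Read and write clinical tables
#'
#' A clinical table is a tibble with one row per sample: `sample_id`, survival
#' columns (`os_time`, `os_event`, optionally `dfs_time`, `dfs_event`),
#' covariates, and a `tissue` label (`"tumor"` or `"normal"`). Event flags are
#' checked to be 0/1 and times non-negative.
#'
#' @param path TSV path.
#' @return a tibble.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_clinical(df)
  df
}

#' @rdname read_clinical
#' @param clinical clinical tibble to write.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}

validate_clinical <- function(df) {
  if (!"sample_id" %in% names(df)) stop("clinical table needs 'sample_id'", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table", call. = FALSE)
  for (ev in intersect(c("os_event", "dfs_event"), names(df))) {
    v <- df[[ev]]
    if (!all(v[!is.na(v)] %in% c(0, 1))) stop(ev, " must be 0/1", call. = FALSE)
  }
  for (tm in intersect(c("os_time", "dfs_time"), names(df))) {
    v <- df[[tm]]
    if (any(v[!is.na(v)] < 0)) stop(tm, " must be non-negative", call. = FALSE)
  }
  invisible(df)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name <TAB> description <TAB> gene...`.
#' Trailing empty fields are ignored. Set names must be unique and every set
#' non-empty.
#'
#' @param path GMT path.
#' @return a named list of character gene vectors, with a `"description"`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    nm <- fields[1L]
    if (nm %in% names(sets)) {
      stop(sprintf("duplicated gene-set name '%s' (GMT line %d)", nm, i),
           call. = FALSE)
    }
    sets[[nm]] <- fields[-(1:2)]
    descs[nm] <- fields[2L]
  }
  attr(sets, "description") <- descs
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors (optionally with a `"description"`
#'   attribute).
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "description")
  if (is.null(descs)) descs <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a cell-type signature matrix
#'
#' Marker genes x cell types, linear scale, non-negative values.
#'
#' @param path TSV path (first column gene ids, header cell types).
#' @return numeric matrix, marker genes x cell types.
#' @export
read_signature <- function(path) {
  m <- read_expression(path, scale = "tpm")
  attr(m, "scale") <- NULL
  if (any(m < 0)) stop("signature matrix must be non-negative", call. = FALSE)
  m
}

#' @rdname read_signature
#' @param signature signature matrix to write.
#' @export
write_signature <- function(signature, path) {
  df <- data.frame(gene_id = rownames(signature), signature,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
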