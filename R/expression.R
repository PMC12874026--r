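#' Construct an expression matrix container
#'
#' Lightweight container for a genes-by-samples expression matrix together
#' with its identifiers and normalization state. All user-facing readers and
#' scorers operate on this class.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of row identifiers (unique after
#'   upper-case folding).
#' @param sample_ids Character vector of column identifiers (unique after
#'   upper-case folding).
#' @param normalized Either `"raw"` (counts or other nonnegative values) or
#'   `"lognorm"` (already log-normalized).
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids` and `normalized`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              normalized = c("raw", "lognorm")) {
  normalized <- match.arg(normalized)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids)) {
    estop("matrix has %d rows but %d gene ids", nrow(values), length(gene_ids))
  }
  if (ncol(values) != length(sample_ids)) {
    estop("matrix has %d columns but %d sample ids",
          ncol(values), length(sample_ids))
  }
  dup <- duplicated(fold_id(gene_ids))
  if (any(dup)) {
    estop("duplicate gene id (case-insensitive): '%s'", gene_ids[dup][1L])
  }
  dup <- duplicated(fold_id(sample_ids))
  if (any(dup)) {
    estop("duplicate sample id (case-insensitive): '%s'", sample_ids[dup][1L])
  }
  check_finite(values, "expression matrix")
  if (normalized == "raw" && any(values < 0)) {
    estop("raw expression values must be nonnegative")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         normalized = normalized),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$normalized))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports two plain-text layouts: a dense delimited table (gene ids in the
#' first column, sample ids in the header row) and a MatrixMarket coordinate
#' file accompanied by gene and sample id files, one identifier per line
#' (10x-style triplet).
#'
#' @param path Path to the dense table or the `.mtx` file.
#' @param format `"dense"` or `"mtx"`. Defaults to `"mtx"` when `path` ends
#'   in `.mtx`, `"dense"` otherwise.
#' @param genes_file,samples_file Identifier files for the MTX triplet.
#' @param transpose For MTX input whose rows are samples rather than genes.
#' @param normalized Normalization state of the stored values; use
#'   `"lognorm"` to ingest a matrix that was normalized upstream.
#'
#' @details The dense delimiter is chosen from the file extension: `.csv`
#'   is comma-separated, anything else tab-separated. Duplicate identifiers
#'   (case-insensitive) are rejected. Zero-variance genes are retained here
#'   and dropped per-analysis by the scorers that require variance.
#'
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = NULL, genes_file = NULL,
                            samples_file = NULL, transpose = FALSE,
                            normalized = c("raw", "lognorm")) {
  normalized <- match.arg(normalized)
  if (!file.exists(path)) estop("expression file not found: '%s'", path)
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  format <- match.arg(format, c("dense", "mtx"))
  if (format == "dense") {
    read_expression_dense(path, normalized)
  } else {
    read_expression_mtx(path, genes_file, samples_file, transpose, normalized)
  }
}

read_expression_dense <- function(path, normalized) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      quote = "", comment.char = "", stringsAsFactors = FALSE),
    error = function(e) estop("failed to parse '%s': %s", path, conditionMessage(e))
  )
  if (ncol(df) < 2L) {
    estop("dense matrix '%s' needs a gene-id column plus >=1 sample column", path)
  }
  gene_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    estop("non-numeric expression values in '%s'", path)
  }
  expression_matrix(vals, gene_ids, colnames(df)[-1L], normalized = normalized)
}

read_expression_mtx <- function(path, genes_file, samples_file, transpose,
                                normalized) {
  if (is.null(genes_file) || is.null(samples_file)) {
    estop("MTX input requires 'genes_file' and 'samples_file'")
  }
  lines <- readLines(path)
  body <- which(!startsWith(lines, "%") & nzchar(trimws(lines)))
  if (length(body) == 0L) estop("MTX file '%s' has no size header", path)
  hdr_line <- body[1L]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[hdr_line]), "\\s+")[[1L]]))
  if (length(hdr) != 3L || anyNA(hdr)) {
    estop("malformed MTX size header at line %d of '%s'", hdr_line, path)
  }
  n_entries <- length(body) - 1L
  if (n_entries != hdr[3L]) {
    estop("MTX header at line %d of '%s' declares %d entries but file contains %d",
          hdr_line, path, hdr[3L], n_entries)
  }
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) estop("failed to parse MTX '%s': %s",
                                          path, conditionMessage(e)))
  m <- as.matrix(m)
  if (transpose) m <- t(m)
  gene_ids <- read_id_file(genes_file)
  sample_ids <- read_id_file(samples_file)
  if (nrow(m) != length(gene_ids)) {
    estop("MTX has %d gene rows but '%s' lists %d ids",
          nrow(m), genes_file, length(gene_ids))
  }
  if (ncol(m) != length(sample_ids)) {
    estop("MTX has %d sample columns but '%s' lists %d ids",
          ncol(m), samples_file, length(sample_ids))
  }
  expression_matrix(m, gene_ids, sample_ids, normalized = normalized)
}

read_id_file <- function(path) {
  if (!file.exists(path)) estop("identifier file not found: '%s'", path)
  ids <- trimws(readLines(path))
  # tolerate 10x-style two-column gene files (id <tab> symbol): keep column 1
  ids <- vapply(strsplit(ids, "\t", fixed = TRUE), `[`, character(1L), 1L)
  ids[nzchar(ids)]
}

#' Write an expression matrix as a dense delimited table
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(x))` round-trips to full double
#' precision.
#'
#' @param x An [expression_matrix()].
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  vals <- apply(x$values, 2L, function(col) sprintf("%.17g", col))
  vals <- matrix(vals, nrow = nrow(x$values))
  out <- cbind(gene_id = x$gene_ids, vals)
  colnames(out) <- c("gene_id", x$sample_ids)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library-size normalize and log-transform an expression matrix
#'
#' Scales each sample (column) to a fixed total, then applies `log1p`.
#' This is the default transformation applied to raw counts before scoring;
#' matrices normalized upstream can be ingested directly with
#' `read_expression(..., normalized = "lognorm")`.
#'
#' @param x A raw [expression_matrix()].
#' @param scale_total Target column sum before the log transform
#'   (default 10,000, counts-per-10k).
#' @return An [expression_matrix()] with `normalized = "lognorm"`.
#' @export
lognormalize <- function(x, scale_total = 1e4) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$normalized != "raw") {
    estop("input is already log-normalized")
  }
  if (!is.numeric(scale_total) || length(scale_total) != 1L || scale_total <= 0) {
    estop("'scale_total' must be a positive number")
  }
  totals <- colSums(x$values)
  zero <- totals == 0
  if (any(zero)) {
    estop("sample '%s' has zero total expression", x$sample_ids[which(zero)[1L]])
  }
  vals <- log1p(sweep(x$values, 2L, totals / scale_total, "/"))
  expression_matrix(vals, x$gene_ids, x$sample_ids, normalized = "lognorm")
}

#' Read per-sample metadata
#'
#' Reads a tab-separated table with a header row; a `sample_id` column is
#' required. Remaining columns carry categorical labels (e.g. time points,
#' cluster ids) or numeric covariates such as pseudotime.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with class `SampleMetadata` prepended.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) estop("metadata file not found: '%s'", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    estop("metadata '%s' lacks a 'sample_id' column", path)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    estop("duplicate sample_id in metadata '%s'", path)
  }
  class(df) <- c("SampleMetadata", class(df))
  df
}

# Align metadata rows to an ordered set of sample ids; errors on mismatch.
align_metadata <- function(meta, sample_ids) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx)) {
    estop("metadata is missing sample '%s'", sample_ids[which(is.na(idx))[1L]])
  }
  meta[idx, , drop = FALSE]
}
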