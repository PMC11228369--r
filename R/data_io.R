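#' Expression matrix container
#'
#' A light S3 wrapper around a non-negative genes x columns numeric matrix.
#' `unit` records the value scale: raw `counts`, `TPM`, or within-cell
#' `rank` after [rank_normalize_cells()].
#'
#' @param values Numeric matrix, genes in rows, cells or samples in columns.
#' @param unit One of `"counts"`, `"TPM"`, `"rank"`.
#' @param dataset_id Identifier of the originating dataset.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, unit = c("counts", "TPM", "rank"),
                              dataset_id = "dataset") {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    values <- rowsum(values, group = rownames(values), reorder = FALSE)
  }
  if (any(!is.finite(values))) stop("expression matrix has non-finite values")
  if (any(values < 0)) stop("expression matrix has negative values")
  structure(
    list(
      gene_ids = rownames(values),
      cell_or_sample_ids = colnames(values),
      values = values,
      unit = unit,
      dataset_id = dataset_id
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %s: %d genes x %d columns [%s]\n",
    x$dataset_id, length(x$gene_ids), length(x$cell_or_sample_ids), x$unit
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports a CellRanger-style MatrixMarket triplet directory
#' (`matrix.mtx`, `features.tsv`/`genes.tsv`, `barcodes.tsv`) or a dense
#' TSV/CSV with gene ids in the first column. Duplicate gene ids are
#' collapsed by summation (conservative for counts); file order is otherwise
#' preserved.
#'
#' @param path Directory (for `mtx_dir`) or file (for `dense_tsv`).
#' @param format `"mtx_dir"` or `"dense_tsv"`.
#' @param unit Value unit recorded on the returned object.
#' @param dataset_id Dataset identifier; defaults to the file/dir name.
#' @param transpose For `dense_tsv`: set TRUE when the file is oriented
#'   columns x genes rather than genes x columns.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, format = c("dense_tsv", "mtx_dir"),
                                   unit = "counts",
                                   dataset_id = NULL,
                                   transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such path: ", path)
  if (is.null(dataset_id)) dataset_id <- basename(path)

  if (format == "mtx_dir") {
    mtx <- .find_one(path, c("matrix.mtx"), "matrix.mtx")
    feat <- .find_one(path, c("features.tsv", "genes.tsv"), "features/genes tsv")
    bars <- .find_one(path, c("barcodes.tsv"), "barcodes.tsv")
    m <- tryCatch(Matrix::readMM(mtx), error = function(e) {
      stop("failed to parse MatrixMarket file ", mtx, ": ", conditionMessage(e))
    })
    genes <- utils::read.table(feat, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(bars, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("dimension mismatch between ", mtx, " (", nrow(m), "x", ncol(m),
           ") and annotation files (", length(genes), " genes, ",
           length(cells), " barcodes)")
    }
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, cells)
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed table ", path, ": need id column plus values")
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric entries in ", path)
    if (anyNA(vals)) {
      idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop("missing value in ", path, " at row ", idx[1], ", column ", idx[2])
    }
    rownames(vals) <- ids
    if (transpose) vals <- t(vals)
  }
  if (any(vals < 0)) stop("negative entries in ", path)
  expression_matrix(vals, unit = unit, dataset_id = dataset_id)
}

.find_one <- function(dir, names, what) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("MTX directory ", dir, " is missing its ", what, " file")
}

#' Write a tabular artifact as TSV
#'
#' Writes a data frame or matrix with a header row. Matrices keep their row
#' names in a leading `id` column so that the round trip through
#' [read_signature_matrix()] / [read_table()] is the identity.
#'
#' @param records Non-empty data frame or matrix.
#' @param path Output path.
#' @param id_column Name used for the row-name column when writing a matrix.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, id_column = "id") {
  if (is.null(records) || NROW(records) == 0L) stop("no records to write")
  if (is.matrix(records)) {
    df <- data.frame(rownames(records), records, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- id_column
    records <- df
  }
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write table to ", path)
  invisible(path)
}

#' Read a tabular artifact written by [write_table()]
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read a signature matrix
#'
#' On disk the signature matrix is a TSV whose first column (`gene_id`)
#' holds gene identifiers and whose remaining columns are exemplar ids.
#'
#' @param sig Numeric matrix, genes x exemplars, dimnames set.
#' @param path TSV path.
#' @return For the reader, the genes x exemplars numeric matrix.
#' @export
write_signature_matrix <- function(sig, path) {
  stopifnot(is.matrix(sig), !is.null(rownames(sig)), !is.null(colnames(sig)))
  write_table(sig, path, id_column = "gene_id")
}

#' @rdname write_signature_matrix
#' @export
read_signature_matrix <- function(path) {
  df <- read_table(path)
  if (ncol(df) < 2L) stop("signature matrix ", path, " has no exemplar columns")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("missing cell in signature matrix ", path, " at row ", idx[1],
         ", column ", idx[2] + 1L)
  }
  rownames(vals) <- as.character(df[[1]])
  vals
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time`, `event` (0/1) and optionally
#' `subtype` and `cohort`.
#'
#' @param path TSV path.
#' @return A data frame with validated `time` and `event`.
#' @export
read_survival_table <- function(path) {
  df <- read_table(path)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("survival table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}
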