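#' Construct and validate an expression matrix
#'
#' The central container at every stage of the pipeline is a plain numeric
#' matrix with genes as rows and cells as columns, carrying unique gene ids as
#' `rownames` and unique cell ids as `colnames`, plus a logical
#' `"log_scaled"` attribute recording whether the values have been
#' log2-rescaled. Keeping a base matrix (rather than a heavier S4 container)
#' means every `stats`/`Matrix` routine applies directly.
#'
#' @param values numeric matrix (genes x cells), finite values.
#' @param gene_ids character vector of unique row ids; defaults to existing
#'   rownames.
#' @param cell_ids character vector of unique column ids; defaults to existing
#'   colnames.
#' @param log_scaled logical, whether values are on log2 scale.
#' @param allow_negative logical; simulated data live on an abstract log-like
#'   scale and may be negative, whereas matrices read from files must be
#'   non-negative.
#' @return the validated matrix with dimnames and the `log_scaled` attribute.
#' @examples
#' m <- expression_matrix(matrix(0:3, 2, 2), c("g1", "g2"), c("c1", "c2"))
#' attr(m, "log_scaled")
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              log_scaled = FALSE, allow_negative = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_srimpute("'values' must be a numeric matrix", "srimpute_validation_error")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%d", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    abort_srimpute("id lengths must match matrix dimensions",
                   "srimpute_validation_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort_srimpute("duplicate gene ids", "srimpute_validation_error")
  }
  if (anyDuplicated(cell_ids)) {
    abort_srimpute("duplicate cell ids", "srimpute_validation_error")
  }
  if (any(!is.finite(values))) {
    abort_srimpute("expression values must be finite (no NA/NaN/Inf)",
                   "srimpute_validation_error")
  }
  if (!allow_negative && any(values < 0)) {
    abort_srimpute("negative expression values are not allowed",
                   "srimpute_validation_error")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  attr(values, "log_scaled") <- isTRUE(log_scaled)
  values
}

#' Read an expression matrix from CSV, TSV or MatrixMarket files
#'
#' Dense CSV/TSV files carry gene ids in the first column and cell ids in the
#' header row. MatrixMarket (`.mtx`) sparse files are accompanied by sidecar
#' id files (one id per line): `genes.txt` for rows and `barcodes.txt` for
#' columns, looked up next to the `.mtx` file unless given explicitly.
#'
#' @param path input file path.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`; guessed from the file
#'   extension when missing.
#' @param genes_file,cells_file sidecar id files for `mtx` input.
#' @param allow_negative allow negative values (default `FALSE`: expression
#'   read from disk must be non-negative).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("csv", "tsv", "mtx"),
                            genes_file = NULL, cells_file = NULL,
                            allow_negative = FALSE) {
  if (!file.exists(path)) {
    abort_srimpute(sprintf("file not found: %s", path), "srimpute_io_error")
  }
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv", "mtx")) ext else "csv"
  }
  format <- match.arg(format)

  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    dt <- tryCatch(
      data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
      error = function(e) abort_srimpute(
        sprintf("failed to parse %s as %s: %s", path, format, conditionMessage(e)),
        "srimpute_parse_error")
    )
    if (ncol(dt) < 1L) {
      abort_srimpute(sprintf("no columns parsed from %s", path),
                     "srimpute_parse_error")
    }
    gene_ids <- as.character(dt[[1L]])
    vals <- dt[, -1L, drop = FALSE]
    not_num <- !vapply(vals, is.numeric, logical(1L))
    if (any(not_num)) {
      abort_srimpute(
        sprintf("non-numeric expression column(s): %s",
                paste(names(vals)[not_num], collapse = ", ")),
        "srimpute_parse_error")
    }
    m <- as.matrix(vals)
    rownames(m) <- gene_ids
    return(expression_matrix(m, allow_negative = allow_negative))
  }

  # MatrixMarket coordinate format, 1-based indices, zeros omitted.
  dir <- dirname(path)
  genes_file <- genes_file %||% file.path(dir, "genes.txt")
  cells_file <- cells_file %||% file.path(dir, "barcodes.txt")
  if (!file.exists(genes_file) || !file.exists(cells_file)) {
    abort_srimpute(
      sprintf("mtx sidecar id files not found (%s, %s)", genes_file, cells_file),
      "srimpute_io_error")
  }
  sp <- tryCatch(Matrix::readMM(path), error = function(e) abort_srimpute(
    sprintf("failed to parse MatrixMarket file %s: %s", path, conditionMessage(e)),
    "srimpute_parse_error"))
  gene_ids <- readLines(genes_file)
  cell_ids <- readLines(cells_file)
  m <- as.matrix(sp)
  expression_matrix(m, gene_ids, cell_ids, allow_negative = allow_negative)
}

#' Write an expression matrix to CSV, TSV or MatrixMarket files
#'
#' Values round-trip through [read_expression()] within 1e-9. For `mtx`
#' output, zero entries are omitted (sparse convention) and the sidecar id
#' files `genes.txt` / `barcodes.txt` are written next to the matrix file
#' unless other paths are given.
#'
#' @inheritParams read_expression
#' @param matrix expression matrix (genes x cells) with dimnames.
#' @export
write_expression <- function(matrix, path, format = c("csv", "tsv", "mtx"),
                             genes_file = NULL, cells_file = NULL) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv", "mtx")) ext else "csv"
  }
  format <- match.arg(format)
  m <- matrix
  if (is.null(rownames(m)) && nrow(m) > 0L) {
    rownames(m) <- sprintf("gene%d", seq_len(nrow(m)))
  }
  if (is.null(colnames(m)) && ncol(m) > 0L) {
    colnames(m) <- sprintf("cell%d", seq_len(ncol(m)))
  }

  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("gene%d", seq_len(nrow(m)))
    df <- data.frame(gene = ids, unclass_expr(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = sep, col.names = TRUE)
    return(invisible(path))
  }

  dir <- dirname(path)
  genes_file <- genes_file %||% file.path(dir, "genes.txt")
  cells_file <- cells_file %||% file.path(dir, "barcodes.txt")
  sp <- methods::as(Matrix::Matrix(unclass_expr(m), sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, path)
  writeLines(rownames(m), genes_file)
  writeLines(colnames(m), cells_file)
  invisible(path)
}

# Strip srimpute attributes so Matrix() coercion sees a plain base matrix.
#' @keywords internal
unclass_expr <- function(m) {
  attr(m, "log_scaled") <- NULL
  m
}

#' Filter genes and rescale an expression matrix
#'
#' Removes genes expressed (value > 0) in fewer than `min_cells` cells and
#' genes whose fraction of non-zero entries is below `min_nonzero_fraction`.
#' If the range (max - min) of the surviving values exceeds `range_threshold`,
#' all values are replaced by `log2(x + 1)` so zeros stay exactly zero; the
#' transform is applied once, globally. Gene order is preserved.
#'
#' @param matrix expression matrix (genes x cells).
#' @param min_cells minimum number of cells with non-zero expression.
#' @param min_nonzero_fraction minimum fraction of non-zero entries per gene.
#' @param range_threshold value range above which the log2 rescale is applied.
#' @return a list with `matrix` (filtered, possibly rescaled) and `report`,
#'   a list with fields `removed_low_cell_genes`, `removed_low_fraction_genes`,
#'   `log_applied` and `original_range`.
#' @examples
#' m <- expression_matrix(rbind(a = c(5, 0, 0), b = c(1, 2, 3)))
#' preprocess(m)$report$removed_low_cell_genes
#' @export
preprocess <- function(matrix, min_cells = 2, min_nonzero_fraction = 0.01,
                       range_threshold = 100) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  nz <- rowSums(matrix != 0)
  frac <- nz / ncol(matrix)
  low_cell <- nz < min_cells
  low_frac <- !low_cell & frac < min_nonzero_fraction
  keep <- !(low_cell | low_frac)
  if (!any(keep)) {
    abort_srimpute(
      "all genes removed by filtering; lower min_cells/min_nonzero_fraction",
      "srimpute_empty_result_error")
  }
  out <- matrix[keep, , drop = FALSE]

  rng <- range(out)
  log_applied <- FALSE
  if (diff(rng) > range_threshold) {
    if (any(out < 0)) {
      abort_srimpute("cannot log-rescale a matrix with negative values",
                     "srimpute_validation_error")
    }
    out <- log2(out + 1)
    log_applied <- TRUE
    if (diff(range(out)) > range_threshold) {
      warning("value range still exceeds range_threshold after log2 rescale")
    }
  }
  attr(out, "log_scaled") <- log_applied || isTRUE(attr(matrix, "log_scaled"))

  list(
    matrix = out,
    report = list(
      removed_low_cell_genes = sum(low_cell),
      removed_low_fraction_genes = sum(low_frac),
      log_applied = log_applied,
      original_range = rng
    )
  )
}
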