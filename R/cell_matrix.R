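#' Single-cell count container
#'
#' Bundles a gene-by-cell matrix of raw integer counts with per-cell
#' metadata. Counts are stored sparse (`dgCMatrix`); metadata rows align
#' with matrix columns via the `barcode` column. Typical metadata columns
#' for photoconversion experiments are `kaede_label` ("green"/"red"),
#' `time_since_label_h`, `condition`, `cluster` and `mito_fraction`.
#'
#' @param counts gene-by-cell matrix of non-negative integers (dense or
#'   sparse). Row names, if present, seed `gene_ids`; column names seed the
#'   barcodes.
#' @param gene_ids character vector of unique gene symbols, one per row.
#' @param cell_metadata data.frame with one row per cell. A `barcode`
#'   column is added from the matrix column names when missing.
#' @return an object of class `cell_matrix` with elements `counts`,
#'   `gene_ids` and `cell_metadata`.
#' @export
#' @examples
#' m <- cell_matrix(matrix(0:5, nrow = 3,
#'                         dimnames = list(c("a", "b", "c"), c("c1", "c2"))))
#' dim(m)
cell_matrix <- function(counts, gene_ids = rownames(counts), cell_metadata = NULL) {
  if (!methods::is(counts, "sparseMatrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(counts, "CsparseMatrix")
  vals <- mat_values(counts)
  if (length(vals) && (any(vals < 0) || any(vals != floor(vals)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("gene_%05d", seq_len(nrow(counts)))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(counts)) {
    stop("length(gene_ids) must equal nrow(counts)", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique", call. = FALSE)
  }
  barcodes <- colnames(counts)
  if (is.null(barcodes)) barcodes <- sprintf("cell_%06d", seq_len(ncol(counts)))
  if (anyDuplicated(barcodes)) stop("cell barcodes must be unique", call. = FALSE)
  if (is.null(cell_metadata)) {
    cell_metadata <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  }
  cell_metadata <- as.data.frame(cell_metadata)
  if (!"barcode" %in% names(cell_metadata)) cell_metadata$barcode <- barcodes
  if (nrow(cell_metadata) != ncol(counts)) {
    stop("cell_metadata must have one row per cell", call. = FALSE)
  }
  if (!identical(as.character(cell_metadata$barcode), barcodes)) {
    stop("cell_metadata barcodes must match matrix columns in order", call. = FALSE)
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  rownames(cell_metadata) <- NULL
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_metadata = cell_metadata),
    class = "cell_matrix"
  )
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Number of cells / genes in a `cell_matrix`
#' @param x a `cell_matrix`.
#' @return integer count.
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) nrow(x$counts)

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat("metadata columns:", paste(names(x$cell_metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a `cell_matrix`
#'
#' @param x a `cell_matrix`.
#' @param genes gene index (integer/logical/character).
#' @param cells cell index (integer/logical/character barcode).
#' @param ... unused.
#' @return a `cell_matrix` restricted to the requested genes and cells,
#'   preserving order.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL, ...) {
  stopifnot(inherits(x, "cell_matrix"))
  counts <- x$counts
  meta <- x$cell_metadata
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(cells)) {
    counts <- counts[, cells, drop = FALSE]
    idx <- match(colnames(counts), meta$barcode)
    meta <- meta[idx, , drop = FALSE]
  }
  cell_matrix(counts, rownames(counts), meta)
}

# mito fraction per cell from a symbol prefix; used when metadata lacks it
mito_fraction_from_counts <- function(x, mito_prefix = "mt-") {
  tot <- Matrix::colSums(x$counts)
  mito <- startsWith(x$gene_ids, mito_prefix)
  frac <- rep(0, ncol(x$counts))
  nz <- tot > 0
  if (any(mito)) {
    frac[nz] <- Matrix::colSums(x$counts[mito, nz, drop = FALSE]) / tot[nz]
  }
  frac
}
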