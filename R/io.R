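#' Gene set
#'
#' @param name set name.
#' @param genes character vector of member symbols; duplicates are
#'   dropped with a warning.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene set must be non-empty", call. = FALSE)
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': dropping duplicate genes", name))
    genes <- unique(genes)
  }
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d genes)\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 50), call. = FALSE)
    }
    gene_set(parts[1], parts[-(1:2)])
  })
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate gene-set names in GMT", call. = FALSE)
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell matrix from MTX triplet files plus metadata
#'
#' Standard single-cell MTX convention: a MatrixMarket coordinate file of
#' gene-by-cell counts (1-based indices in the file, converted
#' internally), a features TSV (gene ids, first column), a barcodes TSV,
#' and an optional per-cell metadata CSV joined on `barcode`.
#'
#' @param path_mtx MatrixMarket file.
#' @param path_features features TSV.
#' @param path_barcodes barcodes TSV.
#' @param path_metadata optional metadata CSV with a `barcode` column
#'   covering every barcode.
#' @return a [cell_matrix()].
#' @export
read_matrix <- function(path_mtx, path_features, path_barcodes,
                        path_metadata = NULL) {
  for (p in c(path_mtx, path_features, path_barcodes)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  counts <- methods::as(Matrix::readMM(path_mtx), "CsparseMatrix")
  features <- utils::read.delim(path_features, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.delim(path_barcodes, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (length(features) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop("dimension mismatch between matrix and features/barcodes", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes", call. = FALSE)
  meta <- NULL
  if (!is.null(path_metadata)) {
    if (!file.exists(path_metadata)) {
      stop("file not found: ", path_metadata, call. = FALSE)
    }
    meta <- utils::read.csv(path_metadata, stringsAsFactors = FALSE)
    if (!"barcode" %in% names(meta)) {
      stop("metadata must have a barcode column", call. = FALSE)
    }
    idx <- match(barcodes, meta$barcode)
    if (anyNA(idx)) {
      stop("metadata missing barcode(s): ",
           paste(utils::head(barcodes[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    meta <- meta[idx, , drop = FALSE]
  }
  colnames(counts) <- barcodes
  cell_matrix(counts, features, meta)
}

#' Write a cell matrix as MTX triplet files plus metadata CSV
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate, 1-based in the file),
#' `features.tsv`, `barcodes.tsv` and `cell_metadata.csv` into a
#' directory.
#'
#' @param x a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cell_matrix <- function(x, dir) {
  stopifnot(inherits(x, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(x$cell_metadata, file.path(dir, "cell_metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
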