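## CellTable: sparse gene x cell UMI counts, labeled-fraction estimates
## (NTR; NA = absent, distinct from 0), and per-cell metadata.

#' Construct a cell table
#'
#' The central single-cell container: UMI counts (sparse, genes x cells),
#' labeled-fraction estimates (`ntr`, the per-gene fraction of newly
#' transcribed mRNA, in \[0,1\], `NA` where not estimated), and per-cell
#' metadata.
#'
#' @param counts gene x cell matrix of non-negative integer UMI counts
#'   (coerced to sparse `dgCMatrix`).
#' @param ntr gene x cell numeric matrix in \[0,1\] with `NA` marking absent
#'   estimates. Must match `counts` in dimension.
#' @param meta data.frame of per-cell records; recognized columns are
#'   `stage`, `cluster`, `pseudotime_au`, `replicate`, and any number of
#'   logical trajectory membership columns.
#' @return an object of class `cell_table`.
#' @export
cell_table <- function(counts, ntr = NULL, meta = NULL) {
  if (!inherits(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts) + 0, sparse = TRUE)
  counts <- methods::as(counts, "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  ng <- nrow(counts); nc <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("gene_%04d", seq_len(ng))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("cell_%05d", seq_len(nc))
  if (!is.null(ntr)) {
    ntr <- as.matrix(ntr)
    if (!all(dim(ntr) == dim(counts)))
      stop("ntr dimensions must match counts", call. = FALSE)
    bad <- !is.na(ntr) & (ntr < 0 | ntr > 1)
    if (any(bad)) stop("ntr values must lie in [0, 1]", call. = FALSE)
    dimnames(ntr) <- dimnames(counts)
  }
  if (is.null(meta)) meta <- data.frame(row.names = colnames(counts))
  if (nrow(meta) != nc) stop("meta must have one row per cell", call. = FALSE)
  rownames(meta) <- colnames(counts)
  if (!is.null(meta$pseudotime_au) && any(meta$pseudotime_au < 0, na.rm = TRUE))
    stop("pseudotime_au must be non-negative", call. = FALSE)
  structure(list(counts = counts, ntr = ntr, meta = meta),
            class = "cell_table")
}

#' @export
dim.cell_table <- function(x) dim(x$counts)

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table>", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  ntr:", if (is.null(x$ntr)) "absent" else
    paste0(sum(!is.na(x$ntr)), " estimates"), "\n")
  cat("  meta columns:", paste(colnames(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a cell table
#'
#' @param x a `cell_table`.
#' @param genes,cells index vectors (logical, integer, or names).
#' @param ... unused.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL, ...) {
  stopifnot(inherits(x, "cell_table"))
  gi <- genes %||% seq_len(nrow(x$counts))
  ci <- cells %||% seq_len(ncol(x$counts))
  cell_table(x$counts[gi, ci, drop = FALSE],
             if (!is.null(x$ntr)) x$ntr[gi, ci, drop = FALSE],
             x$meta[ci, , drop = FALSE])
}

#' Filter cells and build the per-gene usability mask
#'
#' Drops cells expressing fewer than `min_genes_per_cell` genes, then marks
#' which (gene, cell) observations are usable for single-cell-level
#' analyses: at least `min_umi_per_cell_per_gene` UMIs in the cell, for a
#' gene with at least `min_total_umi_per_gene` UMIs across all retained
#' cells. Pseudo-bulk analyses use all counts regardless of the mask.
#'
#' @param table a `cell_table`.
#' @param min_genes_per_cell minimum number of detected genes per cell
#'   (default 500).
#' @param min_umi_per_cell_per_gene minimum UMIs per (gene, cell) pair
#'   (default 3).
#' @param min_total_umi_per_gene minimum total UMIs per gene (default 50).
#' @return list with `table` (cells filtered), `usable` (sparse logical
#'   gene x cell mask), and `gene_ok` (logical per gene).
#' @export
filter_cells_genes <- function(table, min_genes_per_cell = 500,
                               min_umi_per_cell_per_gene = 3,
                               min_total_umi_per_gene = 50) {
  stopifnot(inherits(table, "cell_table"),
            min_genes_per_cell >= 0, min_umi_per_cell_per_gene >= 0,
            min_total_umi_per_gene >= 0)
  genes_per_cell <- Matrix::colSums(table$counts > 0)
  keep <- genes_per_cell >= min_genes_per_cell
  if (!any(keep)) stop("no cell passes the gene-detection threshold", call. = FALSE)
  out <- subset_cells(table, cells = which(keep))
  gene_ok <- Matrix::rowSums(out$counts) >= min_total_umi_per_gene
  usable <- (out$counts >= min_umi_per_cell_per_gene) & gene_ok
  list(table = out, usable = usable, gene_ok = gene_ok)
}

## ---- readers / writers -------------------------------------------------

#' Write a cell table to a directory
#'
#' Counts as MatrixMarket `counts.mtx` with `genes.tsv` / `barcodes.tsv`,
#' labeled fractions as `ntr.tsv` (wide, NA = absent), metadata as
#' `meta.tsv`.
#'
#' @param table a `cell_table`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_table <- function(table, dir) {
  stopifnot(inherits(table, "cell_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(table$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(table$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(table$counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(table$ntr))
    write.table(table$ntr, file.path(dir, "ntr.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
  write.table(table$meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  invisible(dir)
}

#' Read a cell table written by [write_cell_table()]
#'
#' @param dir directory containing `counts.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, and optionally `ntr.tsv` and `meta.tsv`.
#' @return a `cell_table`.
#' @export
read_cell_table <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  ntr <- NULL
  if (file.exists(file.path(dir, "ntr.tsv")))
    ntr <- as.matrix(read.table(file.path(dir, "ntr.tsv"), sep = "\t",
                                header = TRUE, row.names = 1, check.names = FALSE))
  meta <- NULL
  if (file.exists(file.path(dir, "meta.tsv")))
    meta <- read.table(file.path(dir, "meta.tsv"), sep = "\t", header = TRUE,
                       row.names = 1, check.names = FALSE)
  cell_table(counts, ntr, meta)
}
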