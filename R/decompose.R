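## Normalization and maternal/zygotic decomposition of expression at
## single-cell and pseudo-bulk resolution.

new_expression_triplet <- function(total, maternal, zygotic, level, log_base) {
  structure(list(total = total, maternal = maternal, zygotic = zygotic,
                 level = level, log_base = log_base),
            class = "expression_triplet")
}

#' @export
print.expression_triplet <- function(x, ...) {
  cat("<expression_triplet>", nrow(x$total), "genes x", ncol(x$total),
      if (x$level == "cell") "cells" else "groups",
      sprintf("(log base %s)\n", x$log_base))
  invisible(x)
}

#' Normalize total expression per cell
#'
#' Standard library-size normalization: each gene's UMIs are divided by the
#' cell's total UMIs, scaled to `scale` (10,000 by default), and
#' `log1p`-transformed (natural log). Zero counts map to 0.
#'
#' @param table a `cell_table`.
#' @param scale normalization scale factor.
#' @return sparse gene x cell matrix of normalized log expression.
#' @export
normalize_cell_expression <- function(table, scale = 10000) {
  stopifnot(inherits(table, "cell_table"))
  tot <- Matrix::colSums(table$counts)
  if (any(tot == 0)) stop("cell with zero total UMI", call. = FALSE)
  norm <- table$counts %*% Matrix::Diagonal(x = scale / tot)
  dimnames(norm) <- dimnames(table$counts)
  norm@x <- log1p(norm@x)
  norm
}

#' Decompose cell-level expression into maternal and zygotic components
#'
#' Splits each (gene, cell) UMI count by the labeled fraction (NTR): the
#' zygotic component uses `UMI * NTR` effective counts and the maternal
#' component `UMI * (1 - NTR)`, each passed through the same normalization
#' and `log1p` transform as the total. Where the labeled fraction is absent
#' (`NA`) the maternal and zygotic entries are `NA` (never imputed to 0).
#'
#' @param table a `cell_table` with `ntr`.
#' @param scale normalization scale factor.
#' @return an `expression_triplet` (cell level, natural-log `log1p` scale);
#'   on the linear (`expm1`) scale maternal + zygotic = total wherever all
#'   three are defined.
#' @export
decompose_maternal_zygotic <- function(table, scale = 10000) {
  stopifnot(inherits(table, "cell_table"))
  if (is.null(table$ntr)) stop("table has no labeled-fraction (ntr) matrix", call. = FALSE)
  tot <- Matrix::colSums(table$counts)
  if (any(tot == 0)) stop("cell with zero total UMI", call. = FALSE)
  total <- as.matrix(normalize_cell_expression(table, scale))
  counts <- as.matrix(table$counts)
  sf <- rep(scale / tot, each = nrow(counts))
  maternal <- log1p(counts * (1 - table$ntr) * sf)
  zygotic <- log1p(counts * table$ntr * sf)
  ## zero counts carry no transcripts of either kind
  maternal[counts == 0] <- 0
  zygotic[counts == 0] <- 0
  new_expression_triplet(total, maternal, zygotic, "cell", "e(log1p)")
}

## count-weighted pseudo-bulk labeled fraction per group
aggregate_group_ntr <- function(table, grouping) {
  groups <- sort(unique(grouping))
  counts <- as.matrix(table$counts)
  w <- counts
  w[is.na(table$ntr)] <- 0
  num <- counts * table$ntr
  num[is.na(num)] <- 0
  ntr_g <- vapply(groups, function(g) {
    ci <- which(grouping == g)
    n <- rowSums(num[, ci, drop = FALSE])
    d <- rowSums(w[, ci, drop = FALSE])
    ifelse(d > 0, n / d, NA_real_)
  }, numeric(nrow(counts)))
  colnames(ntr_g) <- as.character(groups)
  rownames(ntr_g) <- rownames(counts)
  ntr_g
}

#' Pseudo-bulk expression triplet per cell group
#'
#' Aggregates counts within each group, normalizes each group profile to
#' `scale` (10,000), splits it by the group-level labeled fraction, and
#' log2-transforms, flooring values below `floor` (default -4). The
#' group-level labeled fraction is the count-weighted average of cell NTRs
#' by default; externally estimated group matrices can be supplied instead
#' via `expression` and `ntr`.
#'
#' @param table a `cell_table` (may be `NULL` if `expression` and `ntr`
#'   are supplied).
#' @param grouping per-cell group labels (required with `table`).
#' @param expression optional gene x group matrix of linear expression.
#' @param ntr optional gene x group labeled-fraction matrix.
#' @param scale normalization scale.
#' @param floor log2 floor; use `-Inf` to disable flooring.
#' @return an `expression_triplet` (group level, log2 scale).
#' @export
pseudobulk_expression <- function(table = NULL, grouping = NULL,
                                  expression = NULL, ntr = NULL,
                                  scale = 10000, floor = -4) {
  if (is.null(expression)) {
    stopifnot(inherits(table, "cell_table"), !is.null(grouping),
              length(grouping) == ncol(table$counts))
    groups <- sort(unique(grouping))
    expression <- vapply(groups, function(g)
      Matrix::rowSums(table$counts[, grouping == g, drop = FALSE]),
      numeric(nrow(table$counts)))
    colnames(expression) <- as.character(groups)
    if (is.null(ntr) && !is.null(table$ntr))
      ntr <- aggregate_group_ntr(table, grouping)
  }
  expression <- as.matrix(expression)
  tot <- colSums(expression)
  if (any(tot == 0)) stop("group with zero total expression", call. = FALSE)
  norm <- sweep(expression, 2, scale / tot, `*`)
  total <- apply_floor(log2(norm), floor)
  maternal <- zygotic <- NULL
  if (!is.null(ntr)) {
    ntr <- as.matrix(ntr)
    stopifnot(all(dim(ntr) == dim(expression)))
    maternal <- apply_floor(log2(norm * (1 - ntr)), floor)
    zygotic <- apply_floor(log2(norm * ntr), floor)
  }
  new_expression_triplet(total, maternal, zygotic, "pseudobulk", 2)
}

#' Paired log2 counts-per-million pseudo-bulk expression of two tables
#'
#' Collapses each table to one pseudo-bulk sample and reports per-gene
#' log2 CPM, for pairwise sample comparisons. Zero-count genes, whose log
#' is `-Inf`, are replaced by `floor`.
#'
#' @param table_a,table_b `cell_table`s over the same gene universe.
#' @param floor value replacing `-Inf` for zero-count genes (default -4).
#' @return data.frame with `gene`, `a`, `b`.
#' @export
log2_cpm_pseudobulk <- function(table_a, table_b, floor = -4) {
  stopifnot(inherits(table_a, "cell_table"), inherits(table_b, "cell_table"),
            identical(rownames(table_a$counts), rownames(table_b$counts)))
  one <- function(tb) {
    s <- Matrix::rowSums(tb$counts)
    v <- log2(s / sum(s) * 1e6)
    v[!is.finite(v)] <- floor
    v
  }
  data.frame(gene = rownames(table_a$counts), a = one(table_a), b = one(table_b),
             stringsAsFactors = FALSE)
}

#' Write an expression triplet as wide TSV files
#'
#' One file per component (`total.tsv`, `maternal.tsv`, `zygotic.tsv`),
#' genes in rows.
#'
#' @param triplet an `expression_triplet`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_triplet <- function(triplet, dir) {
  stopifnot(inherits(triplet, "expression_triplet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (comp in c("total", "maternal", "zygotic"))
    if (!is.null(triplet[[comp]]))
      write.table(as.matrix(triplet[[comp]]), file.path(dir, paste0(comp, ".tsv")),
                  sep = "\t", quote = FALSE, col.names = NA)
  invisible(dir)
}
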