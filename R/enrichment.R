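## Gene classification by zygotic fraction, cell-type restriction testing,
## UTR k-mer enrichment against fitted parameters, and generic gene-feature
## association tests.

## one-sided two-sample KS: alternative "x stochastically larger than y"
ks_one_sided <- function(x, y) {
  res <- suppressWarnings(ks.test(x, y, alternative = "less"))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Per-gene zygotic mRNA fraction, quantile bins, and class
#'
#' Each gene's mean labeled fraction is taken across cells carrying at
#' least `min_umi` UMIs of that gene; genes are ranked and cut into
#' `n_bins` equal-count quantile bins, and classed as maternal (fraction
#' below `maternal_max`), zygotic (above `zygotic_min`), or
#' maternal_zygotic in between.
#'
#' @param table a `cell_table` with `ntr`.
#' @param min_umi UMI threshold qualifying a cell (default 3).
#' @param n_bins number of quantile bins (default 10).
#' @param maternal_max,zygotic_min class thresholds on the zygotic
#'   fraction (defaults 0.05 and 0.65).
#' @return data.frame with `gene`, `zygotic_fraction`, `n_cells`,
#'   `quantile_bin`, `class`; genes with no qualifying cell are excluded
#'   and listed in the `"excluded"` attribute.
#' @export
gene_zygotic_fraction_bins <- function(table, min_umi = 3, n_bins = 10,
                                       maternal_max = 0.05, zygotic_min = 0.65) {
  stopifnot(inherits(table, "cell_table"), !is.null(table$ntr))
  counts <- as.matrix(table$counts)
  qual <- counts >= min_umi & !is.na(table$ntr)
  n_cells <- rowSums(qual)
  frac <- rowSums(table$ntr * qual, na.rm = TRUE) / pmax(n_cells, 1)
  keep <- n_cells > 0
  df <- data.frame(gene = rownames(counts)[keep],
                   zygotic_fraction = frac[keep], n_cells = n_cells[keep],
                   stringsAsFactors = FALSE)
  ## equal-count bins within +/- 1 gene, ties broken by rank order
  r <- rank(df$zygotic_fraction, ties.method = "first")
  df$quantile_bin <- as.integer(ceiling(r / nrow(df) * n_bins))
  df$class <- ifelse(df$zygotic_fraction < maternal_max, "maternal",
                     ifelse(df$zygotic_fraction > zygotic_min, "zygotic",
                            "maternal_zygotic"))
  attr(df, "excluded") <- rownames(counts)[!keep]
  df
}

#' Cell-type-restricted expression of maternal or zygotic transcripts
#'
#' For each (gene, cell type), compares the gene's component UMI counts
#' (`UMI * NTR` for zygotic, `UMI * (1 - NTR)` for maternal) in cells of
#' the type against cells outside it with comparable pseudotime (within
#' `pseudotime_window` pseudo-minutes of the in-type pseudotime range),
#' with a one-sided Kolmogorov-Smirnov test requiring higher counts
#' inside. P-values are Bonferroni-corrected over the whole gene x type
#' family and only each gene's most significant type is reported.
#'
#' @param table a `cell_table` with `ntr` and per-cell `cluster` labels
#'   (or pass `cell_types`).
#' @param component `"maternal"` or `"zygotic"`.
#' @param cell_types per-cell type labels.
#' @param pseudo_min per-cell pseudo-minutes (defaults to rescaled
#'   `pseudotime_au`).
#' @param pseudotime_window matching window, pseudo-minutes (default 20).
#' @param alpha significance level on the corrected p (default 0.01).
#' @param min_cells cell types with fewer cells are skipped (default 2).
#' @return data.frame, one row per gene: best cell type, raw and
#'   Bonferroni-adjusted p, and significance flag.
#' @export
celltype_restriction_test <- function(table, component = c("maternal", "zygotic"),
                                      cell_types = table$meta$cluster,
                                      pseudo_min = NULL,
                                      pseudotime_window = 20, alpha = 0.01,
                                      min_cells = 2) {
  component <- match.arg(component)
  stopifnot(inherits(table, "cell_table"), !is.null(table$ntr),
            length(cell_types) == ncol(table$counts))
  if (is.null(pseudo_min))
    pseudo_min <- pseudotime_to_minutes(table$meta$pseudotime_au)
  counts <- as.matrix(table$counts)
  w <- if (component == "zygotic") table$ntr else 1 - table$ntr
  comp <- counts * w
  comp[is.na(comp)] <- 0
  types <- unique(cell_types)
  types <- types[vapply(types, function(ty) sum(cell_types == ty) >= min_cells,
                        logical(1))]
  genes <- rownames(counts)
  recs <- list()
  for (ty in types) {
    inside <- cell_types == ty
    rng <- range(pseudo_min[inside])
    matched <- !inside & pseudo_min >= rng[1] - pseudotime_window &
      pseudo_min <= rng[2] + pseudotime_window
    if (sum(matched) < min_cells) next
    for (gi in seq_along(genes)) {
      ks <- ks_one_sided(comp[gi, inside], comp[gi, matched])
      recs[[length(recs) + 1L]] <-
        data.frame(gene = genes[gi], component = component, cell_type = ty,
                   statistic = ks$statistic, p_raw = ks$p_value,
                   stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, recs)
  if (is.null(df)) return(NULL)
  df$p_adjusted <- pmin(1, df$p_raw * nrow(df))  # Bonferroni over the family
  ## keep each gene's most significant cell type
  df <- df[order(df$gene, df$p_adjusted, df$p_raw), ]
  df <- df[!duplicated(df$gene), ]
  df$significant <- df$p_adjusted < alpha
  rownames(df) <- NULL
  df
}

#' Distinct k-mers per gene from its longest UTR
#'
#' Keeps the single longest UTR per gene (records sharing a gene name are
#' collapsed to the longest), drops UTRs shorter than `min_utr_len`, and
#' emits the set of distinct k-mers present for each k in `k_range`.
#' Sequences are uppercased and T is treated as U. Records with other
#' non-nucleotide characters are skipped with a warning.
#'
#' @param utrs named character vector or `XStringSet` of UTR sequences.
#' @param k_range k-mer lengths (default 3:8).
#' @param min_utr_len minimum UTR length (default 10).
#' @return named list: gene -> character vector of distinct k-mers. Dropped
#'   gene names are in the `"dropped"` attribute.
#' @export
extract_utr_kmers <- function(utrs, k_range = 3:8, min_utr_len = 10) {
  if (inherits(utrs, "XStringSet")) utrs <- as.character(utrs)
  stopifnot_named(utrs, "utrs")
  utrs <- chartr("Tt", "Uu", toupper(utrs))
  ## longest record per gene
  ord <- order(nchar(utrs), decreasing = TRUE)
  utrs <- utrs[ord][!duplicated(names(utrs)[ord])]
  bad <- grepl("[^ACGU]", utrs)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-nucleotide characters skipped")
    utrs <- utrs[!bad]
  }
  short <- nchar(utrs) < min_utr_len
  dropped <- names(utrs)[short]
  utrs <- utrs[!short]
  out <- lapply(utrs, function(s) {
    L <- nchar(s)
    unique(unlist(lapply(k_range[k_range <= L], function(k)
      substring(s, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1)),
      use.names = FALSE))
  })
  attr(out, "dropped") <- dropped
  out
}

#' k-mer enrichment against a fitted kinetic parameter
#'
#' For every k-mer, compares the parameter values of carrier genes against
#' non-carriers by a one-sided Kolmogorov-Smirnov test in both directions,
#' keeping the smaller p with its sign (the doubled family is accounted
#' for in the FDR). The effect size is the standardized mean difference
#' `theta = (mu_carrier - mu_noncarrier) / sigma_pooled` with the SD taken
#' over both populations together. A k-mer is called significant when its
#' Benjamini-Hochberg q-value is below `fdr` and `|theta|` reaches
#' `effect_threshold`.
#'
#' @param kmer_sets gene -> k-mer sets from [extract_utr_kmers()].
#' @param parameter_values named per-gene values of the tested parameter
#'   (e.g. log2 half-life, onset time, or log2 initial level).
#' @param fdr FDR threshold (default 0.01).
#' @param effect_threshold minimum `|theta|` (default 0.13).
#' @param min_carriers k-mers with fewer carriers or non-carriers are
#'   skipped (default 2).
#' @return data.frame, one row per tested k-mer: `kmer`, `k`,
#'   `n_carriers`, `statistic`, `p_value`, `q_value`, `theta`,
#'   `significant`.
#' @export
kmer_parameter_enrichment <- function(kmer_sets, parameter_values, fdr = 0.01,
                                      effect_threshold = 0.13,
                                      min_carriers = 2) {
  genes <- intersect(names(kmer_sets), names(parameter_values))
  genes <- genes[is.finite(parameter_values[genes])]
  if (length(genes) < 2 * min_carriers)
    stop("not enough genes with both k-mers and parameter values", call. = FALSE)
  vals <- parameter_values[genes]
  sets <- kmer_sets[genes]
  idx <- data.frame(
    kmer = unlist(sets, use.names = FALSE),
    gene = rep(seq_along(genes), lengths(sets)))
  carriers <- split(idx$gene, idx$kmer)
  n <- length(genes)
  keep <- lengths(carriers) >= min_carriers &
    lengths(carriers) <= n - min_carriers
  carriers <- carriers[keep]
  res <- lapply(names(carriers), function(km) {
    ci <- carriers[[km]]
    x <- vals[ci]; y <- vals[-ci]
    hi <- ks_one_sided(x, y)   # carriers larger
    lo <- ks_one_sided(y, x)   # carriers smaller
    use_hi <- hi$p_value <= lo$p_value
    p <- if (use_hi) hi$p_value else lo$p_value
    stat <- if (use_hi) hi$statistic else -lo$statistic
    theta <- (mean(x) - mean(y)) / sd(vals)
    data.frame(kmer = km, k = nchar(km), n_carriers = length(ci),
               statistic = stat, p_value = p, theta = theta,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  ## both directions were examined per k-mer: double the family for BH
  df$q_value <- p.adjust(df$p_value, method = "BH", n = 2 * nrow(df))
  df$significant <- df$q_value < fdr & abs(df$theta) >= effect_threshold
  rownames(df) <- NULL
  df[order(df$p_value), ]
}

#' Associate a numeric gene feature with a gene set or parameter
#'
#' Generic two-sample association of per-gene features (polyA-tail length,
#' codon optimality, translation efficiency, ...) with either a gene set
#' (logical grouping) or the high/low halves of a fitted parameter (median
#' split). Tests are one-sided KS (larger in group) or two-sided Wilcoxon;
#' p-values are BH-adjusted across the supplied features.
#'
#' @param features named numeric vector (one feature) or a named list of
#'   such vectors.
#' @param grouping logical per-gene vector (in set / out of set), or a
#'   named numeric parameter vector to split at its median.
#' @param test `"ks_one_sided"` or `"wilcoxon"`.
#' @param fdr FDR threshold for the `significant` flag (default 0.01).
#' @return data.frame, one row per feature: `statistic`, `p_value`,
#'   `q_value`, `significant`.
#' @export
feature_association_test <- function(features, grouping,
                                     test = c("ks_one_sided", "wilcoxon"),
                                     fdr = 0.01) {
  test <- match.arg(test)
  if (!is.list(features)) features <- list(feature = features)
  one <- function(f) {
    genes <- intersect(names(f), names(grouping))
    f <- f[genes]
    grp <- grouping[genes]
    if (!is.logical(grp)) grp <- grp > median(grp, na.rm = TRUE)
    ok <- is.finite(f) & !is.na(grp)
    f <- f[ok]; grp <- grp[ok]
    if (sum(grp) < 2 || sum(!grp) < 2)
      return(data.frame(statistic = NA_real_, p_value = NA_real_))
    if (sd(f) == 0)
      return(data.frame(statistic = 0, p_value = 1))
    if (test == "ks_one_sided") {
      r <- ks_one_sided(f[grp], f[!grp])
      data.frame(statistic = r$statistic, p_value = r$p_value)
    } else {
      r <- suppressWarnings(wilcox.test(f[grp], f[!grp]))
      data.frame(statistic = unname(r$statistic), p_value = r$p.value)
    }
  }
  df <- do.call(rbind, lapply(features, one))
  df <- cbind(data.frame(feature = names(features), stringsAsFactors = FALSE), df)
  df$q_value <- p.adjust(df$p_value, method = "BH")
  df$significant <- !is.na(df$q_value) & df$q_value < fdr
  rownames(df) <- NULL
  df
}
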