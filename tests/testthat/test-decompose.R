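test_that("cell filtering applies detection thresholds and builds the mask", {
  tab <- toy_table()
  # cell c2 expresses 2 genes; with threshold 3 it is dropped
  flt <- filter_cells_genes(tab, min_genes_per_cell = 3,
                            min_umi_per_cell_per_gene = 3,
                            min_total_umi_per_gene = 50)
  expect_false("c2" %in% colnames(flt$table$counts))
  # brute-force the mask over all remaining entries
  counts <- as.matrix(flt$table$counts)
  gene_ok <- rowSums(counts) >= 50
  expect_equal(unname(flt$gene_ok), unname(gene_ok))
  for (g in seq_len(nrow(counts)))
    for (ce in seq_len(ncol(counts)))
      expect_equal(flt$usable[g, ce], counts[g, ce] >= 3 && gene_ok[g])
  # zero thresholds are the identity
  flt0 <- filter_cells_genes(tab, 0, 0, 0)
  expect_equal(dim(flt0$table), dim(tab))
  expect_true(all(flt0$gene_ok))
  expect_error(filter_cells_genes(tab, min_genes_per_cell = 10), "no cell")
})

test_that("cell normalization follows the log1p convention", {
  tab <- toy_table()
  norm <- normalize_cell_expression(tab)
  # cell c1: gA has 100 of 1000 UMIs -> log1p(100/1000 * 1e4)
  expect_equal(norm["gA", "c1"], log1p(1000))
  expect_equal(norm["gC", "c1"], 0)  # zero counts map to 0
  # doubling every count in a cell leaves values unchanged
  tab2 <- toy_table()
  tab2$counts[, 1] <- tab2$counts[, 1] * 2
  expect_equal(normalize_cell_expression(tab2)[, 1], norm[, 1])
})

test_that("maternal/zygotic decomposition conserves counts and handles edge NTRs", {
  tab <- toy_table()
  trip <- decompose_maternal_zygotic(tab)
  # UMI 100, NTR 0.3 in a 1000-UMI cell: maternal from 70, zygotic from 30
  expect_equal(trip$maternal["gA", "c1"], log1p(70 / 1000 * 1e4))
  expect_equal(trip$zygotic["gA", "c1"], log1p(30 / 1000 * 1e4))
  # NTR 0 -> zygotic 0, maternal equals total; NTR 1 -> the reverse
  expect_equal(trip$zygotic["gA", "c4"], 0)
  expect_equal(trip$maternal["gA", "c4"], trip$total["gA", "c4"])
  expect_equal(trip$maternal["gA", "c3"], 0)
  expect_equal(trip$zygotic["gA", "c3"], trip$total["gA", "c3"])
  # absent NTR with positive counts propagates as NA, never imputed
  expect_true(is.na(trip$maternal["gB", "c2"]))
  expect_true(is.na(trip$zygotic["gB", "c2"]))
  # zero counts carry no transcripts of either kind
  expect_equal(trip$maternal["gB", "c3"], 0)
  # linear-scale conservation wherever defined
  err <- abs(expm1(trip$maternal) + expm1(trip$zygotic) - expm1(trip$total))
  expect_lt(max(err, na.rm = TRUE), 1e-10)
  # out-of-range ntr is rejected at construction
  bad_ntr <- tab$ntr; bad_ntr[1, 1] <- 1.5
  expect_error(cell_table(tab$counts, bad_ntr), "\\[0, 1\\]")
})

test_that("pseudo-bulk triplet matches hand computation through the equations", {
  # two genes, two groups; work the numbers by hand
  counts <- matrix(c(30, 10,
                     70, 90), 2, 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ntr <- matrix(c(0.2, 0.5,
                  0.8, 1.0), 2, 2, byrow = TRUE, dimnames = dimnames(counts))
  trip <- pseudobulk_expression(expression = counts, ntr = ntr)
  # g1 in s1: 30/100 * 1e4 = 3000; total = log2(3000)
  expect_equal(trip$total["g1", "s1"], log2(3000))
  expect_equal(trip$maternal["g1", "s1"], log2(3000 * 0.8))
  expect_equal(trip$zygotic["g1", "s1"], log2(3000 * 0.2))
  # ntr 1: maternal is log2(0) -> floored at -4
  expect_equal(trip$maternal["g2", "s2"], -4)
  # half split: maternal and zygotic equal, one below total
  expect_equal(trip$maternal["g1", "s2"], trip$zygotic["g1", "s2"])
  expect_equal(trip$total["g1", "s2"] - trip$maternal["g1", "s2"], 1)
  # flooring: abundance 2^-10/1e4 of the group lands below -4
  counts2 <- matrix(c(1, 2^20), 2, 1,
                    dimnames = list(c("lo", "hi"), "s"))
  t2 <- pseudobulk_expression(expression = counts2)
  expect_equal(t2$total["lo", "s"], -4)
  expect_error(pseudobulk_expression(expression = matrix(0, 1, 1)), "zero total")
})

test_that("group-level ntr is the count-weighted average of cell ntr", {
  tab <- toy_table()
  grp <- c("x", "x", "y", "y")
  trip <- pseudobulk_expression(tab, grouping = grp, floor = -Inf)
  # group x, gene gA: cells c1 (100 UMI, ntr .3) and c2 (0 UMI) -> ntr .3
  counts <- as.matrix(tab$counts)
  exp_ntr <- sum(counts["gA", 1:2] * tab$ntr["gA", 1:2], na.rm = TRUE) /
    sum(counts["gA", 1:2][!is.na(tab$ntr["gA", 1:2])])
  norm <- sum(counts["gA", 1:2]) / sum(counts[, 1:2]) * 1e4
  expect_equal(trip$zygotic["gA", "x"], log2(norm * exp_ntr))
  # pseudo-bulk of a single cell reproduces that cell's composition
  one <- pseudobulk_expression(subset_cells(tab, cells = 1),
                               grouping = "only", floor = -Inf)
  expect_equal(2^one$total["gA", "only"], 100 / 1000 * 1e4)
})

test_that("per-cell normalized linear values sum to the scale constant", {
  fx <- small_synth(n_genes = 30, n_cells = 100)
  flt <- filter_cells_genes(fx$table, 1, 0, 0)
  norm <- normalize_cell_expression(flt$table)
  sums <- Matrix::colSums(expm1(norm))
  expect_equal(unname(sums), rep(1e4, ncol(norm)), tolerance = 1e-8)
})

test_that("paired log2 CPM pseudo-bulk behaves on known counts", {
  counts <- matrix(c(1, 2, 1e6 - 3), 3, 1,
                   dimnames = list(c("g1", "g2", "g3"), "c"))
  tab <- cell_table(counts)
  res <- log2_cpm_pseudobulk(tab, tab)
  expect_equal(res$a[1], 0)      # 1 UMI of 1e6 -> 1 CPM -> log2 = 0
  expect_equal(res$a[2], 1)      # 2 UMI -> log2 2 = 1
  expect_equal(res$a, res$b)     # identical tables -> identical vectors
  expect_equal(cor(res$a, res$b), 1)
})
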