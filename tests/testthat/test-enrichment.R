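test_that("zygotic-fraction classes follow the thresholds and bins are balanced", {
  fx <- small_synth(n_genes = 60, n_cells = 600)
  zf <- gene_zygotic_fraction_bins(fx$table)
  expect_true(all(zf$class[zf$zygotic_fraction > 0.65] == "zygotic"))
  expect_true(all(zf$class[zf$zygotic_fraction < 0.05] == "maternal"))
  expect_true(all(zf$class[zf$zygotic_fraction >= 0.05 &
                           zf$zygotic_fraction <= 0.65] == "maternal_zygotic"))
  # quantile bins are equal-count within +/- 1 gene and cover the gene set
  counts <- table(zf$quantile_bin)
  expect_lte(diff(range(counts)), 1)
  expect_equal(sum(counts), nrow(zf))
  # maternal-only truth genes land in the maternal class
  cls <- vapply(fx$truth, `[[`, character(1), "gene_class")
  mo <- vapply(fx$truth[cls == "maternal_only"], `[[`, character(1), "gene_id")
  got <- zf$class[zf$gene %in% mo]
  expect_gt(mean(got == "maternal"), 0.8)
})

test_that("cell-type restriction test finds a planted marker", {
  set.seed(12)
  ng <- 15; nc <- 300
  counts <- matrix(rpois(ng * nc, 3), ng, nc,
                   dimnames = list(sprintf("g%02d", 1:ng),
                                   sprintf("c%03d", 1:nc)))
  types <- rep(c("evl", "deep"), length.out = nc)
  # gene g01 zygotic counts dominate inside "evl"
  counts[1, types == "evl"] <- rpois(sum(types == "evl"), 12)
  ntr <- matrix(runif(ng * nc, 0.4, 0.6), ng, nc, dimnames = dimnames(counts))
  meta <- data.frame(cluster = types, pseudotime_au = runif(nc, 0.1, 2),
                     row.names = colnames(counts))
  tab <- cell_table(counts, ntr, meta)
  res <- celltype_restriction_test(tab, "zygotic")
  r1 <- res[res$gene == "g01", ]
  expect_equal(r1$cell_type, "evl")
  expect_true(r1$significant)
  # identical distributions stay non-significant after Bonferroni
  expect_lt(mean(res$significant[res$gene != "g01"]), 0.1)
  # Bonferroni arithmetic: adjusted = raw * family size (genes x types)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 2 * ng), tolerance = 1e-12)
})

test_that("k-mer extraction keeps the longest UTR and matches a substring oracle", {
  utrs <- c(gA = "GCACUUA", gB = "ACGUACGUACGU", gA = "ACG",
            gC = "ACGUACGU", gD = "ACGNACGUACGU")
  expect_warning(ks <- extract_utr_kmers(utrs, k_range = 3), "skipped")
  # gA keeps its 7-nt record... which is below 10 nt -> dropped
  expect_false("gA" %in% names(ks))
  expect_true("gA" %in% attr(ks, "dropped"))
  expect_false("gC" %in% names(ks))   # 8 nt < 10
  expect_false("gD" %in% names(ks))   # non-nucleotide characters
  expect_equal(sort(ks$gB), sort(c("ACG", "CGU", "GUA", "UAC")))
  # sliding-window example
  ks2 <- extract_utr_kmers(c(g = "GCACUUAGCA"), k_range = 3)
  expect_true(all(c("GCA", "CAC", "ACU", "CUU", "UUA") %in% ks2$g))
  # presence sets agree with a naive substring oracle on random sequences
  pk <- plant_kmer_sequences(30, "GCACUU", 0.5, length_range = c(20, 60),
                             rng_seed = 4)
  ks3 <- extract_utr_kmers(pk$sequences, k_range = 3:8)
  for (g in sample(names(ks3), 8)) {
    s <- pk$sequences[[g]]
    L <- nchar(s)
    oracle <- unique(unlist(lapply(3:8, function(k)
      if (L >= k) substring(s, 1:(L - k + 1), k:L))))
    expect_setequal(ks3[[g]], oracle)
    expect_lte(length(ks3[[g]]), sum(pmax(L - (3:8) + 1, 0)))
  }
  # T handled as U
  expect_equal(extract_utr_kmers(c(g = "ACGTACGTACGT"), k_range = 4)$g,
               extract_utr_kmers(c(g = "ACGUACGUACGU"), k_range = 4)$g)
})

test_that("k-mer enrichment recovers a planted destabilizing motif", {
  pk <- plant_kmer_sequences(300, "UAUUUA", 0.3, rng_seed = 6)
  set.seed(6)
  hl <- rnorm(300, 5, 0.5)
  hl[pk$carrier] <- hl[pk$carrier] - sd(hl)
  names(hl) <- names(pk$sequences)
  ks <- extract_utr_kmers(pk$sequences, k_range = 6)
  res <- kmer_parameter_enrichment(ks, hl)
  hit <- res[res$kmer == "UAUUUA", ]
  expect_true(hit$significant)
  expect_lt(hit$theta, -0.5)       # carriers have shorter half-lives
  expect_lt(hit$q_value, 0.01)
  # theta is invariant under affine transforms of the parameter
  res2 <- kmer_parameter_enrichment(ks, 3 * hl + 7)
  expect_equal(res2$theta[match(res$kmer, res2$kmer)], res$theta,
               tolerance = 1e-9)
  # a shift of one pooled SD gives theta close to 1 in magnitude
  expect_gt(abs(hit$theta), 0.6)
  # permuting parameter values across genes removes the signal
  perm_sig <- vapply(1:10, function(i) {
    hp <- setNames(sample(hl), names(hl))
    rp <- kmer_parameter_enrichment(ks, hp)
    rp$significant[rp$kmer == "UAUUUA"]
  }, logical(1))
  expect_lte(mean(perm_sig), 0.1)
})

test_that("feature association tests detect monotone relations and stay calibrated", {
  set.seed(14)
  n <- 200
  param <- rnorm(n)
  names(param) <- sprintf("g%03d", 1:n)
  # feature tracking the parameter is detected via median split
  feat <- param + rnorm(n, 0, 0.3)
  names(feat) <- names(param)
  res <- feature_association_test(feat, param)
  expect_true(res$significant)
  # identical groups are non-significant; constant features give p = 1
  grp <- setNames(rep(c(TRUE, FALSE), each = n / 2), names(param))
  res2 <- feature_association_test(setNames(rep(1, n), names(param)), grp)
  expect_equal(res2$p_value, 1)
  # wilcoxon route works
  res3 <- feature_association_test(feat, grp, test = "wilcoxon")
  expect_false(res3$significant)
  # false-positive rate under independence stays near nominal
  fp <- vapply(1:100, function(i) {
    f <- setNames(rnorm(n), names(param))
    feature_association_test(f, grp, test = "wilcoxon")$p_value
  }, numeric(1))
  expect_lte(mean(fp < 0.05), 0.11)
})
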