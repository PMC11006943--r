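test_that("parameter grids enumerate the Cartesian product deterministically", {
  g <- build_parameter_grid(list(beta = c(1, 2), x0 = 3, d = c(4, 5, 6)))
  expect_equal(nrow(g), 6)
  # first parameter varies fastest; enumerate by hand
  expect_equal(g$beta, rep(c(1, 2), 3))
  expect_equal(g$d, rep(c(4, 5, 6), each = 2))
  expect_equal(nrow(build_parameter_grid(list(a = 1, b = 2))), 1)
  expect_equal(nrow(default_maternal_grid()), 125)
  expect_error(build_parameter_grid(list(beta = numeric(0))), "beta")
})

test_that("binned profile simulation is deterministic and noise scales correctly", {
  truth <- list(gene_truth("g1", "maternal_only",
                           maternal = list(x0 = 2^7, beta = log(2) / 30, d = 270)),
                gene_truth("g2", "silent"))
  bins <- default_centers()
  a <- simulate_binned_profiles(truth, bins, noise_multiplier = 1, rng_seed = 5)
  b <- simulate_binned_profiles(truth, bins, noise_multiplier = 1, rng_seed = 5)
  expect_identical(a, b)
  z <- simulate_binned_profiles(truth, bins, noise_multiplier = 0, rng_seed = 5)
  expect_equal(z$noisy$maternal, z$noiseless$maternal)
  # silent gene sits at the floor
  expect_true(all(z$noiseless$maternal["g2", ] == -4))
  expect_true(all(z$noiseless$zygotic["g2", ] == -4))
  # noiseless curve equals the analytic model
  expect_equal(unname(z$noiseless$maternal["g1", ]),
               evaluate_maternal(truth[[1]]$maternal, bins))
})

test_that("injected noise has the requested standard deviation", {
  truth <- rep(list(gene_truth("g", "maternal_only",
                               maternal = list(x0 = 2^8, beta = log(2) / 40, d = 260))),
               10000)
  sm <- uniform_sigma_model(0.3, "maternal")
  sim <- simulate_binned_profiles(truth, c(250, 300), sigma_model = sm,
                                  noise_multiplier = 1, rng_seed = 9)
  resid <- sim$noisy$maternal[, 1] - sim$noiseless$maternal[, 1]
  expect_lt(abs(sd(resid) / 0.3 - 1), 0.05)
})

test_that("simulated cell tables honour the data model", {
  fx <- small_synth()
  tab <- fx$table
  expect_s3_class(tab, "cell_table")
  expect_equal(dim(tab), c(60, 400))
  # determinism: same config twice is byte-identical
  fx2 <- small_synth()
  expect_identical(as.matrix(tab$counts), as.matrix(fx2$table$counts))
  expect_identical(tab$ntr, fx2$table$ntr)

  cls <- vapply(fx$truth, `[[`, character(1), "gene_class")
  ntr <- tab$ntr
  counts <- as.matrix(tab$counts)
  # maternal-only genes: labeled fractions concentrated near 0
  mo <- which(cls == "maternal_only")
  vals <- ntr[mo, ][counts[mo, ] >= 3 & !is.na(ntr[mo, ])]
  expect_gt(mean(vals < 0.3), 0.9)
  # zygotic-only genes: labeled fractions near 1 where expressed
  zo <- which(cls == "zygotic_only")
  vz <- ntr[zo, ][counts[zo, ] >= 3 & !is.na(ntr[zo, ])]
  expect_gt(mean(vz > 0.7), 0.9)
  # ntr only defined where counts are positive
  expect_true(all(is.na(ntr[counts == 0])))
})

test_that("pseudo-bulk of an MZ gene approaches its expected zygotic share", {
  # single maternal-zygotic gene among stable companions; late-window cells
  truth <- c(list(gene_truth("mz", "maternal_zygotic",
                             maternal = list(x0 = 2^6, beta = log(2) / 30, d = 250),
                             zygotic = list(alpha = 0.05, d = 250))),
             lapply(1:20, function(i)
               gene_truth(sprintf("bg%02d", i), "maternal_only",
                          maternal = list(x0 = 2^7, beta = 1e-4, d = 350))))
  cfg <- synth_config(n_genes = 21, n_cells = 4000, seed = 13)
  tab <- simulate_cell_table(truth, cfg)
  pm <- tab$meta$pseudo_min
  late <- which(pm > 340)
  tmid <- mean(pm[late])
  m <- truth[[1]]$maternal; z <- truth[[1]]$zygotic
  expect_frac <- z$alpha * (tmid - z$d) /
    (m$x0 * exp(-m$beta * (tmid - m$d)) + z$alpha * (tmid - z$d))
  counts <- as.matrix(tab$counts)[1, late]
  ntr <- tab$ntr[1, late]
  obs <- sum(counts * ntr, na.rm = TRUE) / sum(counts[!is.na(ntr)])
  expect_lt(abs(obs - expect_frac), 0.05)
})

test_that("pseudo-bulk of many simulated cells converges to the generating curves", {
  fx <- small_synth(n_genes = 60, n_cells = 5000, seed = 23)
  spec <- bin_spec()
  prof <- binned_profile(fx$table, spec, pseudo_min = fx$table$meta$pseudo_min)
  # expected normalized curves: per-bin share of each component, scaled to 10^4
  bins <- spec$centers
  M <- t(vapply(fx$truth, function(g) mztkin:::truth_linear(g, bins, "maternal"),
                numeric(length(bins))))
  Z <- t(vapply(fx$truth, function(g) mztkin:::truth_linear(g, bins, "zygotic"),
                numeric(length(bins))))
  tot <- colSums(M + Z)
  expM <- pmax(log2(sweep(M, 2, tot, `/`) * 1e4), -4)
  expZ <- pmax(log2(sweep(Z, 2, tot, `/`) * 1e4), -4)
  # compare where the component is well expressed
  sel <- expM > -2 & !is.na(prof$maternal)
  expect_lt(median(abs(prof$maternal[sel] - expM[sel])), 0.2)
  selz <- expZ > -2 & !is.na(prof$zygotic)
  expect_lt(median(abs(prof$zygotic[selz] - expZ[selz])), 0.2)
})

test_that("planted k-mer sequences obey carrier guarantees", {
  pk <- plant_kmer_sequences(100, "UGUAUAU", 0.5, rng_seed = 3)
  expect_equal(sum(pk$carrier), 50)
  expect_true(all(grepl("UGUAUAU", pk$sequences[pk$carrier], fixed = TRUE)))
  expect_false(any(grepl("UGUAUAU", pk$sequences[!pk$carrier], fixed = TRUE)))
  expect_error(plant_kmer_sequences(10, "ACGT", 0.5), "A/C/G/U")
  expect_error(plant_kmer_sequences(10, "AC", 0.5), "3..8")

  # background occurrence rate of an unrelated 5-mer ~ (L-4) * 4^-5
  pk2 <- plant_kmer_sequences(2000, "GCACUU", 0.01, length_range = c(200, 200),
                              rng_seed = 8)
  bg <- pk2$sequences[!pk2$carrier]
  hits <- vapply(bg, function(s) {
    m <- gregexpr("AAGUC", s, fixed = TRUE)[[1]]
    sum(m > 0)
  }, numeric(1))
  expect_lt(abs(mean(hits) / ((200 - 4) * 4^-5) - 1), 0.15)
})

test_that("writers round-trip tables and emit standard formats", {
  fx <- small_synth(n_genes = 20, n_cells = 50)
  dir <- tempfile()
  write_cell_table(fx$table, dir)
  back <- read_cell_table(dir)
  expect_equal(as.matrix(back$counts), as.matrix(fx$table$counts))
  expect_equal(back$ntr, fx$table$ntr, tolerance = 1e-12)
  expect_equal(back$meta$stage, fx$table$meta$stage)
  fa <- tempfile(fileext = ".fa")
  pk <- plant_kmer_sequences(5, "GCACUU", 0.4, rng_seed = 1)
  write_fasta(pk$sequences, fa)
  rt <- Biostrings::readRNAStringSet(fa)
  expect_equal(as.character(rt), pk$sequences)
  yml <- tempfile(fileext = ".yaml")
  write_truth_yaml(fx$truth, yml)
  loaded <- yaml::read_yaml(yml)
  expect_equal(length(loaded), 20)
  expect_equal(loaded[[1]]$gene_id, fx$truth[[1]]$gene_id)
  unlink(dir, recursive = TRUE)
})
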