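# Small in-code fixtures shared across test files.

# 3-gene x 4-cell toy table with hand-checkable counts and labeled fractions
toy_table <- function() {
  counts <- matrix(c(
    100, 0, 3, 10,
    900, 5, 0, 40,
    0,   5, 7, 50), nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:4)))
  ntr <- matrix(c(
    0.3, NA,  1,  0,
    0.5, NA,  NA, 0.25,
    NA,  0.8, 0,  0.5), nrow = 3, byrow = TRUE,
    dimnames = dimnames(counts))
  ntr[counts == 0] <- NA
  meta <- data.frame(stage = c("dome", "dome", "epb30", "epb50"),
                     cluster = c("ecto", "ecto", "meso", "meso"),
                     pseudotime_au = c(0.05, 0.3, 0.6, 1.0),
                     replicate = c("A", "B", "A", "B"),
                     row.names = colnames(counts))
  cell_table(counts, ntr, meta)
}

# moderately sized synthetic table with known truth
small_synth <- function(n_genes = 60, n_cells = 400, seed = 7, ...) {
  truth <- simulate_gene_truth(n_genes, rng_seed = seed)
  tab <- simulate_cell_table(truth, synth_config(n_genes = n_genes,
                                                 n_cells = n_cells,
                                                 seed = seed, ...))
  list(truth = truth, table = tab)
}

default_centers <- function() bin_spec()$centers
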