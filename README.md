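# mztkin

Kinetics of maternal and zygotic mRNA from metabolically labeled
single-cell RNA-seq.

During the maternal-to-zygotic transition, an embryo clears maternally
deposited transcripts while its own genome activates. Metabolic labeling
(4sU, read out as T-to-C conversions) tags newly transcribed mRNA, and an
upstream estimator turns the conversion signal into a per-gene, per-cell
*labeled fraction* (NTR) — the share of a gene's transcripts that are
zygotic. `mztkin` is for researchers who have such data (a UMI count
matrix, an NTR matrix, per-cell pseudotime) and want quantitative
per-gene regulatory rates out of it.

## What it computes

Expression is decomposed into maternal and zygotic components
(`UMI·(1−NTR)` and `UMI·NTR` through standard normalization), aggregated
over 11 overlapping pseudotime bins spanning 240–360 pseudo-minutes, and
fit per gene to nested kinetic models on the log2 scale:

- maternal decay: `log2 M(t) = log2 x0 − β (t−d)⁺ log2 e`
  (initial level `x0`, decay pseudo-rate `β`, onset `d`;
  pseudo-half-life `ln 2 / β`), nested above a constant and a null model;
- zygotic accumulation: `log2 Z(t) = log2 α + log2(t−d)`
  (accumulation pseudo-rate `α`, onset `d`), with a saturating
  three-parameter variant `log2 α − log2 β_z + log2(1 − e^{−β_z(t−d)})`.

Model selection climbs each nested chain by likelihood-ratio tests
(`n·ln(RSS₀/RSS₁)` vs. chi-square). Around the core fit the package
provides replicate-based noise calibration and chi-square goodness-of-fit
testing, gene classification and A–D kinetic grouping, trajectory-specific
regulation tests (uniform vs. two-parameter-set models), UTR k-mer
enrichment against fitted parameters (one-sided KS + standardized mean
difference θ), and a fully deterministic synthetic-data generator with
known ground truth that makes the whole pipeline testable offline.

## Worked example

```r
library(mztkin)

truth <- simulate_gene_truth(120, rng_seed = 42)
tab <- simulate_cell_table(truth, synth_config(n_genes = 120,
                                               n_cells = 2000, seed = 42))
tab
#> <cell_table> 120 genes x 2000 cells
#>   ntr: 185965 estimates
#>   meta columns: stage, pseudotime_au, pseudo_min, replicate

flt <- filter_cells_genes(tab, min_genes_per_cell = 20)
prof <- binned_profile(flt$table, pseudo_min = flt$table$meta$pseudo_min)
prof
#> <binned_profile> 120 genes x 11 bins; centers 246.5 256.5 ... 336.5 350

kin <- fit_gene_kinetics(prof, n_starts = 60, rng_seed = 1)
table(kin$gene_class)
#>    maternal_only maternal_zygotic            unfit     zygotic_only
#>               54               25                7               34

summary(kin$half_life_pseudo_min[kin$maternal_model == "M_decay"])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   20.19   27.77   34.93   85.70   91.10  504.96
```

The class table reports which components carried a non-null selected
model: here 54 genes look purely maternal, 34 purely zygotic, and 25 show
both a decaying maternal and an accumulating zygotic component (matching
the generator's class mix). `half_life_pseudo_min` is `ln 2 / β` and is
defined only for genes where the decay model beat the constant model.
Maternal-zygotic genes additionally receive a group A–D from fast/slow
half-life (bounds 20/45 pseudo-minutes) crossed with fast/slow log2
accumulation; the accumulation bounds default to the real-data scale
(−12/−11) and should be adapted to the expression scale at hand
(`fit_gene_kinetics(..., log2_alpha_bounds = ...)`).

A one-call version of the same flow, with outputs and a reproducibility
manifest written to disk:

```r
run_pipeline(pipeline_config(synthetic = list(n_genes = 120, n_cells = 2000),
                             seed = 42, min_genes_per_cell = 20),
             output_dir = "out")
```

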