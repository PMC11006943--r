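## Configuration-driven orchestration of the full analysis with a
## reproducibility manifest.

#' Build a pipeline configuration
#'
#' Collects every stage's thresholds with their standard defaults. Supply
#' either `input_dir` (a directory readable by [read_cell_table()]) or a
#' `synthetic` block (arguments for [synth_config()]); the synthetic route
#' also draws ground-truth kinetics via [simulate_gene_truth()].
#'
#' @param input_dir optional directory with counts/ntr/meta tables.
#' @param synthetic optional list of [synth_config()] arguments.
#' @param seed integer master seed.
#' @param min_genes_per_cell,min_umi_per_cell_per_gene,min_total_umi_per_gene
#'   filtering thresholds (see [filter_cells_genes()]).
#' @param bin_step,bin_width pseudotime binning (see [bin_spec()]).
#' @param alpha_level,n_starts model selection settings.
#' @param half_life_bounds,log2_alpha_bounds gene grouping bounds.
#' @param trajectory_p,trajectory_r2,trajectory_effect_bounds
#'   trajectory-call thresholds.
#' @param kmer_fdr,kmer_effect k-mer enrichment thresholds.
#' @param floor log2 expression floor.
#' @return a `pipeline_config` list; round-trips through YAML unchanged.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = NULL, seed = 1,
                            min_genes_per_cell = 50,
                            min_umi_per_cell_per_gene = 3,
                            min_total_umi_per_gene = 50,
                            bin_step = 10, bin_width = 13,
                            alpha_level = 0.05, n_starts = 100,
                            half_life_bounds = c(20, 45),
                            log2_alpha_bounds = c(-12, -11),
                            trajectory_p = 0.01, trajectory_r2 = 0.8,
                            trajectory_effect_bounds = c(0.5, 2),
                            kmer_fdr = 0.01, kmer_effect = 0.13,
                            floor = -4) {
  if (is.null(input_dir) && is.null(synthetic))
    synthetic <- list()
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file of [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Stages in order: data acquisition (read or simulate), cell/gene
#' filtering, maternal/zygotic decomposition, pseudotime binning, kinetic
#' model fitting and classification, replicate noise calibration and
#' goodness-of-fit, trajectory-specific tests (when trajectory metadata is
#' present), and zygotic-fraction classification. Results are written as
#' TSVs under `output_dir` together with a `manifest.yaml` recording the
#' package version, seed, config hash, and per-stage row counts; rerunning
#' with the same config reproduces all outputs.
#'
#' @param config a `pipeline_config` (or path to its YAML).
#' @param output_dir output directory.
#' @return invisibly, a list with the main result objects.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "mztkin",
                   version = as.character(utils::packageVersion("mztkin")),
                   seed = config$seed, config_hash = config_hash(config),
                   stages = list())

  ## acquire
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir))
      stop("input directory not found: ", config$input_dir, call. = FALSE)
    table <- read_cell_table(config$input_dir)
    truth <- NULL
  } else {
    sc <- do.call(synth_config, c(config$synthetic, list(seed = config$seed)))
    truth <- simulate_gene_truth(sc$n_genes, rng_seed = child_seed(config$seed, 1))
    table <- simulate_cell_table(truth, sc)
    write_truth_yaml(truth, file.path(output_dir, "truth.yaml"))
  }
  manifest$stages$acquire <- list(genes = nrow(table$counts),
                                  cells = ncol(table$counts))

  ## filter + decompose
  flt <- filter_cells_genes(table, config$min_genes_per_cell,
                            config$min_umi_per_cell_per_gene,
                            config$min_total_umi_per_gene)
  table <- flt$table
  manifest$stages$filter <- list(cells = ncol(table$counts),
                                 genes_ok = sum(flt$gene_ok))
  triplet <- decompose_maternal_zygotic(table)
  manifest$stages$decompose <- list(entries = sum(!is.na(triplet$maternal)))

  ## bin
  spec <- bin_spec(step = config$bin_step, width = config$bin_width)
  profile <- binned_profile(table, spec, floor = config$floor)
  write.table(profile$maternal, file.path(output_dir, "binned_maternal.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(profile$zygotic, file.path(output_dir, "binned_zygotic.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  manifest$stages$bin <- list(bins = spec$n_bins,
                              cells_per_bin = profile$n_cells)

  ## fit kinetics
  kin <- fit_gene_kinetics(profile, alpha_level = config$alpha_level,
                           n_starts = config$n_starts,
                           rng_seed = child_seed(config$seed, 2),
                           floor = config$floor,
                           half_life_bounds = config$half_life_bounds,
                           log2_alpha_bounds = config$log2_alpha_bounds)
  write.table(kin, file.path(output_dir, "kinetics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$fit <- list(genes = nrow(kin),
                              classes = as.list(table(kin$gene_class)))

  ## diagnose: replicate sigma + stage-level goodness of fit
  gof <- NULL
  reps <- unique(table$meta$replicate)
  if (length(reps) >= 2) {
    pm <- pseudotime_to_minutes(table$meta$pseudotime_au)
    trips <- lapply(reps[1:2], function(r) {
      sub <- subset_cells(table, cells = which(table$meta$replicate == r))
      pseudobulk_expression(sub, grouping = sub$meta$stage,
                            floor = config$floor)
    })
    shared <- intersect(colnames(trips[[1]]$total), colnames(trips[[2]]$total))
    if (length(shared) >= 1 && nrow(kin) >= 10) {
      align <- function(tr) {
        for (cmp in c("total", "maternal", "zygotic"))
          tr[[cmp]] <- tr[[cmp]][, shared, drop = FALSE]
        tr
      }
      sig_m <- estimate_replicate_sigma(align(trips[[1]]), align(trips[[2]]),
                                        "maternal",
                                        n_groups = min(6, nrow(kin) %/% 2))
      anchors <- stage_pseudotimes()
      stages <- intersect(names(anchors), unique(table$meta$stage))
      if (length(stages) >= 1) {
        obs <- pseudobulk_expression(table, grouping = table$meta$stage,
                                     floor = config$floor)
        fitted_genes <- kin$gene[kin$maternal_model == "M_decay"]
        if (length(fitted_genes)) {
          om <- obs$maternal[fitted_genes, stages, drop = FALSE]
          pred <- t(vapply(fitted_genes, function(g) {
            r <- kin[kin$gene == g, ]
            evaluate_maternal(list(x0 = r$x0, beta = r$beta, d = r$d_m),
                              anchors[stages])
          }, numeric(length(stages))))
          me <- rowMeans(om, na.rm = TRUE)
          gof <- goodness_of_fit(om, pred, sigma_lookup(sig_m, me),
                                 floor = config$floor)
          gof <- cbind(gene = fitted_genes, gof)
          write.table(gof, file.path(output_dir, "goodness_of_fit.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          manifest$stages$diagnose <-
            list(tested = nrow(gof), retained = sum(gof$retained))
        }
      }
    }
  }

  ## trajectory tests (when trajectory metadata columns exist)
  traj <- NULL
  tcols <- grep("^traj_", colnames(table$meta), value = TRUE)
  if (length(tcols)) {
    cells <- colnames(table$counts)
    sets <- lapply(tcols, function(cn) cells[table$meta[[cn]]])
    names(sets) <- tcols
    ts <- prepare_trajectories(sets, table, spec)
    rows <- list()
    for (tn in names(ts$trajectories)) {
      prof2 <- trajectory_binned_profiles(table, ts$trajectories[[tn]], spec,
                                          floor = config$floor)
      for (cmp in c("maternal", "zygotic")) {
        r <- test_trajectory_genes(prof2, cmp, n_starts = config$n_starts,
                                   rng_seed = child_seed(config$seed, 3),
                                   floor = config$floor)
        if (!is.null(r) && nrow(r)) {
          r$trajectory <- tn
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
    if (length(rows)) {
      traj <- call_trajectory_specific(do.call(rbind, rows),
                                       p_threshold = config$trajectory_p,
                                       r2_threshold = config$trajectory_r2,
                                       effect_bounds = config$trajectory_effect_bounds)
      write.table(traj, file.path(output_dir, "trajectory_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$trajectory <-
        list(tested = nrow(traj),
             specific = sum(traj$call != "uniform"))
    }
  }

  ## zygotic-fraction classification
  zf <- gene_zygotic_fraction_bins(table,
                                   min_umi = config$min_umi_per_cell_per_gene)
  write.table(zf, file.path(output_dir, "zygotic_fraction.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$enrich <- list(genes = nrow(zf),
                                 classes = as.list(table(zf$class)))

  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  invisible(list(table = table, truth = truth, profile = profile,
                 kinetics = kin, goodness_of_fit = gof, trajectory = traj,
                 zygotic_fraction = zf, manifest = manifest))
}

## stable hash of the configuration (md5 of its serialized form)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  x <- unclass(config)
  saveRDS(x[order(names(x))], tmp, version = 2)
  unname(tools::md5sum(tmp))
}
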