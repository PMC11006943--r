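## Synthetic data with known ground truth: parameter grids, binned noisy
## profiles, full cell-level tables, and UTR sequences with planted k-mers.

#' Enumerate a Cartesian parameter grid
#'
#' @param values_per_parameter named list mapping each parameter to its
#'   ordered value list; five values per parameter of a three-parameter
#'   model yield 125 sets.
#' @return a `simulation_grid` data.frame, one row per combination, in
#'   deterministic order (first parameter varies fastest).
#' @export
build_parameter_grid <- function(values_per_parameter) {
  stopifnot_named(values_per_parameter, "values_per_parameter")
  for (nm in names(values_per_parameter))
    if (!length(values_per_parameter[[nm]]))
      stop("empty value list for parameter '", nm, "'", call. = FALSE)
  g <- expand.grid(values_per_parameter, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  class(g) <- c("simulation_grid", class(g))
  g
}

#' Default maternal-decay simulation grid
#'
#' Five values per parameter of the three-parameter decay model (125 sets):
#' initial levels spanning moderately to highly expressed genes, half-lives
#' from 15 to 160 pseudo-minutes, and onsets inside the observed window so
#' that the onset is identifiable.
#' @return a `simulation_grid` with columns `x0`, `beta`, `d`.
#' @export
default_maternal_grid <- function() {
  build_parameter_grid(list(
    x0 = 2^c(4, 5.5, 7, 8.5, 10),
    beta = log(2) / c(15, 25, 40, 80, 160),
    d = c(250, 270, 290, 310, 330)))
}

#' Default zygotic-accumulation simulation grid
#'
#' Five accumulation rates and five onsets for the two-parameter linear
#' model (25 sets), chosen so profiles rise well above the expression
#' floor within the window.
#' @return a `simulation_grid` with columns `alpha`, `d`.
#' @export
default_zygotic_grid <- function() {
  build_parameter_grid(list(
    alpha = 2^c(-5, -4, -3, -2, -1),
    d = c(245, 260, 275, 290, 305)))
}

#' Ground-truth kinetics for one synthetic gene
#'
#' @param gene_id identifier.
#' @param gene_class one of `maternal_only`, `zygotic_only`,
#'   `maternal_zygotic`, `silent`.
#' @param maternal list `(x0, beta, d)` or `NULL`.
#' @param zygotic list `(alpha, d [, beta_z])` or `NULL`.
#' @param trajectory_effect optional list `(trajectory, component, params)`
#'   giving an alternate parameter set used for cells inside the named
#'   trajectory.
#' @return a `gene_truth`.
#' @export
gene_truth <- function(gene_id, gene_class, maternal = NULL, zygotic = NULL,
                       trajectory_effect = NULL) {
  gene_class <- match.arg(gene_class, c("maternal_only", "zygotic_only",
                                        "maternal_zygotic", "silent"))
  if (gene_class == "silent" && (!is.null(maternal) || !is.null(zygotic)))
    stop("silent genes carry no parameters", call. = FALSE)
  if (!is.null(maternal)) stopifnot(maternal$beta > 0, maternal$d >= 0,
                                    maternal$d <= 360)
  if (!is.null(zygotic)) stopifnot(zygotic$alpha > 0, zygotic$d >= 0,
                                   zygotic$d <= 360)
  structure(list(gene_id = gene_id, gene_class = gene_class,
                 maternal = maternal, zygotic = zygotic,
                 trajectory_effect = trajectory_effect),
            class = "gene_truth")
}

#' Draw a random set of ground-truth genes
#'
#' Classes are drawn with the given probabilities; maternal parameters use
#' initial levels 2^3--2^10, half-lives 15--160 pseudo-minutes and onsets
#' 245--330; zygotic parameters use accumulation rates 2^-6--2^-1 and
#' onsets 245--310.
#'
#' @param n_genes number of genes.
#' @param class_probs probabilities for (maternal_only, zygotic_only,
#'   maternal_zygotic, silent).
#' @param rng_seed integer seed.
#' @return list of `gene_truth`.
#' @export
simulate_gene_truth <- function(n_genes,
                                class_probs = c(maternal_only = 0.3,
                                                zygotic_only = 0.25,
                                                maternal_zygotic = 0.4,
                                                silent = 0.05),
                                rng_seed = 1) {
  with_seed(rng_seed, {
    cls <- sample(names(class_probs), n_genes, replace = TRUE,
                  prob = class_probs)
    lapply(seq_len(n_genes), function(i) {
      m <- z <- NULL
      if (cls[i] %in% c("maternal_only", "maternal_zygotic"))
        m <- list(x0 = 2^runif(1, 3, 10),
                  beta = log(2) / exp(runif(1, log(15), log(160))),
                  d = runif(1, 245, 330))
      if (cls[i] %in% c("zygotic_only", "maternal_zygotic"))
        z <- list(alpha = 2^runif(1, -6, -1), d = runif(1, 245, 310))
      gene_truth(sprintf("gene_%04d", i), cls[i], m, z)
    })
  })
}

## truth curves at arbitrary times, per component (linear scale)
truth_linear <- function(truth, t, component, in_trajectory = FALSE) {
  pars <- truth[[component]]
  te <- truth$trajectory_effect
  if (in_trajectory && !is.null(te) && te$component == component)
    pars <- te$params
  if (is.null(pars)) return(numeric(length(t)))
  if (component == "maternal") {
    pars$x0 * exp(-pars$beta * pmax(0, t - pars$d))
  } else {
    dt <- pmax(0, t - pars$d)
    if (is.null(pars$beta_z)) pars$alpha * dt
    else pars$alpha / pars$beta_z * (1 - exp(-pars$beta_z * dt))
  }
}

#' Simulate noisy binned kinetic profiles
#'
#' Evaluates each gene's model curves (log2 scale) at the bin centers and
#' adds Normal noise with SD equal to `noise_multiplier` times the gene's
#' expression-group SD. Multipliers `{0.5, 1, 1.5}` correspond to noise at
#' half, at, and one-and-a-half times the calibrated SD. Both the noisy
#' profile (floored) and its noiseless twin are returned.
#'
#' @param truth list of `gene_truth`.
#' @param bins bin centers, pseudo-minutes (sorted ascending).
#' @param sigma_model expression-group noise model (or `NULL` for the
#'   component default).
#' @param noise_multiplier SD multiplier (0 gives noiseless output).
#' @param rng_seed integer seed; the same seed reproduces the output
#'   exactly.
#' @param floor log2 floor; silent/absent components emit the floor.
#' @return list with `noisy` and `noiseless`, each holding gene x bin
#'   matrices `maternal` and `zygotic`.
#' @export
simulate_binned_profiles <- function(truth, bins, sigma_model = NULL,
                                     noise_multiplier = 1, rng_seed = 1,
                                     floor = -4) {
  stopifnot(!is.unsorted(bins))
  ids <- vapply(truth, `[[`, character(1), "gene_id")
  mk <- function(component) {
    sm <- sigma_model %||% default_sigma_model(component)
    clean <- t(vapply(truth, function(g) {
      v <- truth_linear(g, bins, component)
      pmax(log2(pmax(v, 0)), floor)
    }, numeric(length(bins))))
    rownames(clean) <- ids
    colnames(clean) <- sprintf("bin_%02d", seq_along(bins))
    sig <- sigma_lookup(sm, rowMeans(clean))
    noise <- matrix(rnorm(length(clean), 0, noise_multiplier * rep(sig, ncol(clean))),
                    nrow(clean), ncol(clean))
    list(noiseless = clean, noisy = pmax(clean + noise, floor))
  }
  with_seed(rng_seed, {
    m <- mk("maternal")
    z <- mk("zygotic")
    list(noisy = list(maternal = m$noisy, zygotic = z$noisy),
         noiseless = list(maternal = m$noiseless, zygotic = z$noiseless),
         centers = bins)
  })
}

#' Synthetic-dataset configuration
#'
#' Defaults emulate an early-embryo dissociation time course: cells spread
#' uniformly over 240--360 pseudo-minutes; three stages anchored at 260,
#' 310 and 340 pseudo-minutes (cells assigned to the nearest anchor);
#' log-normal library sizes around 5000 UMIs; negative-binomial UMI counts
#' with mild overdispersion; Beta-distributed labeled-fraction estimates
#' around the true new/total ratio; two replicates.
#'
#' @param n_genes,n_cells dataset dimensions.
#' @param pseudotime_range pseudo-minute range.
#' @param stage_anchors named stage pseudotimes.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param nb_size negative-binomial size (dispersion = 1/size).
#' @param ntr_concentration Beta concentration of labeled-fraction noise;
#'   larger is less noisy.
#' @param replicate_levels replicate labels assigned uniformly.
#' @param trajectory_fraction fraction of cells flagged as belonging to the
#'   synthetic trajectory `traj_1` (0 disables).
#' @param seed integer seed fixing the complete output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 200, n_cells = 1000,
                         pseudotime_range = c(240, 360),
                         stage_anchors = stage_pseudotimes(),
                         libsize_meanlog = log(5000), libsize_sdlog = 0.3,
                         nb_size = 10, ntr_concentration = 30,
                         replicate_levels = c("A", "B"),
                         trajectory_fraction = 0, seed = 1) {
  stopifnot(pseudotime_range[1] < pseudotime_range[2], n_genes > 0,
            n_cells > 0, nb_size > 0, ntr_concentration > 0,
            libsize_sdlog >= 0, trajectory_fraction >= 0,
            trajectory_fraction < 1)
  structure(list(n_genes = n_genes, n_cells = n_cells,
                 pseudotime_range = pseudotime_range,
                 stage_anchors = stage_anchors,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, nb_size = nb_size,
                 ntr_concentration = ntr_concentration,
                 replicate_levels = replicate_levels,
                 trajectory_fraction = trajectory_fraction, seed = seed),
            class = "synth_config")
}

#' Simulate a full cell-level table from ground-truth kinetics
#'
#' Per cell: a pseudotime is drawn uniformly in range; each gene's expected
#' maternal and zygotic abundance comes from its truth curves at that
#' pseudotime (cells flagged as in-trajectory use a gene's alternate
#' parameter set when a `trajectory_effect` is present); UMI counts are
#' negative-binomial around the gene's relative abundance times the cell's
#' library size; the labeled fraction is the true zygotic share perturbed
#' by Beta noise, defined only where counts are positive.
#'
#' @param truth list of `gene_truth` (length `config$n_genes`).
#' @param config a [synth_config()].
#' @return a `cell_table` with `stage`, `pseudotime_au`, `pseudo_min`,
#'   `replicate`, and (when enabled) `traj_1` metadata columns.
#' @export
simulate_cell_table <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"),
            length(truth) == config$n_genes)
  with_seed(config$seed, {
    nc <- config$n_cells; ng <- config$n_genes
    rng <- config$pseudotime_range
    pt <- runif(nc, rng[1], rng[2])
    in_traj <- if (config$trajectory_fraction > 0)
      runif(nc) < config$trajectory_fraction else rep(FALSE, nc)
    M <- t(vapply(truth, function(g) truth_linear(g, pt, "maternal"),
                  numeric(nc)))
    Z <- t(vapply(truth, function(g) truth_linear(g, pt, "zygotic"),
                  numeric(nc)))
    if (any(in_traj)) {
      ti <- which(in_traj)
      for (gi in seq_along(truth)) {
        te <- truth[[gi]]$trajectory_effect
        if (is.null(te)) next
        alt <- truth_linear(truth[[gi]], pt[ti], te$component, in_trajectory = TRUE)
        if (te$component == "maternal") M[gi, ti] <- alt else Z[gi, ti] <- alt
      }
    }
    tot <- M + Z
    share <- sweep(tot, 2, pmax(colSums(tot), .Machine$double.eps), `/`)
    lib <- rlnorm(nc, config$libsize_meanlog, config$libsize_sdlog)
    mu <- sweep(share, 2, lib, `*`)
    counts <- matrix(rnbinom(ng * nc, mu = mu, size = config$nb_size), ng, nc)
    frac <- ifelse(tot > 0, Z / tot, NA_real_)
    ntr <- matrix(NA_real_, ng, nc)
    pos <- which(counts > 0 & !is.na(frac))
    f <- frac[pos]
    kappa <- config$ntr_concentration
    noisy <- numeric(length(f))
    mid <- f > 0 & f < 1
    noisy[mid] <- rbeta(sum(mid), f[mid] * kappa, (1 - f[mid]) * kappa)
    noisy[f == 0] <- 0
    noisy[f == 1] <- 1
    ntr[pos] <- clamp(noisy, 0, 1)
    anchors <- config$stage_anchors
    stage <- names(anchors)[apply(abs(outer(pt, anchors, `-`)), 1, which.min)]
    meta <- data.frame(
      stage = stage,
      pseudotime_au = (pt - rng[1]) / (rng[2] - rng[1]),
      pseudo_min = pt,
      replicate = sample(config$replicate_levels, nc, replace = TRUE),
      stringsAsFactors = FALSE)
    if (config$trajectory_fraction > 0) meta$traj_1 <- in_traj
    ids <- vapply(truth, `[[`, character(1), "gene_id")
    rownames(counts) <- ids
    colnames(counts) <- sprintf("cell_%05d", seq_len(nc))
    cell_table(counts, ntr, meta)
  })
}

#' Random UTR sequences with a planted k-mer
#'
#' Generates random-background RNA sequences; a fixed fraction of them
#' (carriers) contain at least one copy of the planted k-mer, while
#' non-carriers are guaranteed free of it (chance occurrences are rejected
#' and redrawn).
#'
#' @param n_genes number of sequences.
#' @param kmer RNA string over A/C/G/U, length 3--8.
#' @param carrier_fraction fraction of carrier sequences (0 < f < 1);
#'   `round(n_genes * carrier_fraction)` carriers are produced.
#' @param length_range sequence length range, nucleotides.
#' @param rng_seed integer seed.
#' @return list with `sequences` (named character vector) and `carrier`
#'   (logical truth labels).
#' @export
plant_kmer_sequences <- function(n_genes, kmer, carrier_fraction,
                                 length_range = c(100, 300), rng_seed = 1) {
  k <- nchar(kmer)
  if (k < 3 || k > 8) stop("kmer length must be 3..8", call. = FALSE)
  if (grepl("[^ACGU]", kmer)) stop("kmer alphabet must be A/C/G/U", call. = FALSE)
  stopifnot(carrier_fraction > 0, carrier_fraction < 1)
  n_carrier <- round(n_genes * carrier_fraction)
  with_seed(rng_seed, {
    lens <- length_range[1] +
      floor(runif(n_genes) * (length_range[2] - length_range[1] + 1))
    carrier <- c(rep(TRUE, n_carrier), rep(FALSE, n_genes - n_carrier))
    seqs <- vapply(seq_len(n_genes), function(i) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "U"), lens[i], replace = TRUE),
                   collapse = "")
        if (carrier[i]) {
          pos <- sample.int(lens[i] - k + 1, 1)
          s <- paste0(substr(s, 1, pos - 1), kmer, substr(s, pos + k, lens[i]))
          return(s)
        }
        if (!grepl(kmer, s, fixed = TRUE)) return(s)
      }
    }, character(1))
    names(seqs) <- sprintf("gene_%04d", seq_len(n_genes))
    list(sequences = seqs, carrier = carrier)
  })
}

#' Write sequences as FASTA
#' @param sequences named character vector (RNA or DNA).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::RNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write ground-truth parameters as YAML
#' @param truth list of `gene_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(lapply(truth, function(g)
    list(gene_id = g$gene_id, gene_class = g$gene_class,
         maternal = g$maternal, zygotic = g$zygotic,
         trajectory_effect = g$trajectory_effect)), path)
  invisible(path)
}
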