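## Trajectory-specific regulation: merge overlapping lineages, fit a
## two-parameter-set "specific" model against a shared "uniform" model per
## gene, and call specific regulation on p-value, fit quality, and effect.

#' Merge overlapping trajectories and check bin coverage
#'
#' Pairs of trajectories sharing more than `overlap_threshold` of the
#' smaller set's cells are merged iteratively until a fixed point (the
#' result is independent of processing order). Trajectories whose in- or
#' out-of-trajectory cells populate fewer than `min_bins` pseudotime bins
#' are dropped as ineligible.
#'
#' @param cell_sets named list of cell identifier vectors.
#' @param table a `cell_table` whose cells contain all set members.
#' @param spec a [bin_spec()].
#' @param pseudo_min optional per-cell pseudo-minutes (defaults to the
#'   rescaled `meta$pseudotime_au`).
#' @param overlap_threshold merge threshold on the smaller set (default 0.5).
#' @param min_bins minimum bins with cells, inside and outside (default 6).
#' @param min_cells_per_bin cells needed for a bin to count as estimated.
#' @return a `trajectory_set`: list with `trajectories` (merged, eligible),
#'   `dropped`, and `merges` (character log).
#' @export
prepare_trajectories <- function(cell_sets, table, spec = bin_spec(),
                                 pseudo_min = NULL, overlap_threshold = 0.5,
                                 min_bins = 6, min_cells_per_bin = 1) {
  stopifnot_named(cell_sets, "cell_sets")
  cells <- colnames(table$counts)
  for (nm in names(cell_sets))
    if (!all(cell_sets[[nm]] %in% cells))
      stop("trajectory '", nm, "' contains unknown cells", call. = FALSE)
  sets <- lapply(cell_sets, unique)
  merges <- character(0)
  repeat {
    done <- TRUE
    nms <- names(sets)
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j <= i) next
        ov <- length(intersect(sets[[i]], sets[[j]])) /
          min(length(sets[[i]]), length(sets[[j]]))
        if (ov > overlap_threshold) {
          merged_name <- paste(nms[i], nms[j], sep = "+")
          merges <- c(merges, merged_name)
          sets[[i]] <- union(sets[[i]], sets[[j]])
          names(sets)[i] <- merged_name
          sets[[j]] <- NULL
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) break
  }
  if (is.null(pseudo_min))
    pseudo_min <- pseudotime_to_minutes(table$meta$pseudotime_au)
  names(pseudo_min) <- cells
  memb <- assign_bins(pseudo_min, spec)
  eligible <- vapply(sets, function(s) {
    inside <- cells %in% s
    bins_in <- colSums(memb[inside, , drop = FALSE]) >= min_cells_per_bin
    bins_out <- colSums(memb[!inside, , drop = FALSE]) >= min_cells_per_bin
    sum(bins_in) >= min_bins && sum(bins_out) >= min_bins
  }, logical(1))
  structure(list(trajectories = sets[eligible],
                 dropped = names(sets)[!eligible], merges = merges,
                 spec = spec),
            class = "trajectory_set")
}

#' Binned profiles inside and outside one trajectory
#'
#' @param table a `cell_table`.
#' @param traj_cells cell identifiers belonging to the trajectory.
#' @param spec a [bin_spec()].
#' @param ... passed to [binned_profile()].
#' @return list with `inside` and `outside` `binned_profile`s.
#' @export
trajectory_binned_profiles <- function(table, traj_cells, spec = bin_spec(), ...) {
  cells <- colnames(table$counts)
  inside <- cells %in% traj_cells
  list(inside = binned_profile(subset_cells(table, cells = which(inside)),
                               spec = spec, ...),
       outside = binned_profile(subset_cells(table, cells = which(!inside)),
                                spec = spec, ...))
}

#' Uniform vs trajectory-specific kinetic model for one gene
#'
#' The uniform null fits one parameter set jointly to the concatenated
#' inside + outside observations; the specific alternative fits independent
#' parameter sets to each side. They are compared by a likelihood-ratio
#' test with degrees of freedom equal to one parameter set.
#'
#' @param y_in,t_in log2 observations and times inside the trajectory.
#' @param y_out,t_out observations and times outside.
#' @param model_id kinetic model used on both sides (e.g. `"M_decay"`).
#' @param n_starts,rng_seed,floor passed to [fit_kinetic_model()].
#' @return list with `uniform_fit`, `inside_fit`, `outside_fit`,
#'   `rss_specific`, `r2_specific`, `lrt_statistic`, `df`, `p_value`, and
#'   `effect_size` (see [trajectory_effect_size()]); `p_value` is `NA` with
#'   `unfit = TRUE` when either side cannot be fit.
#' @export
fit_trajectory_models <- function(y_in, t_in, y_out, t_out, model_id,
                                  n_starts = 100, rng_seed = 1, floor = -4) {
  ok_in <- is.finite(y_in); ok_out <- is.finite(y_out)
  y_in <- y_in[ok_in]; t_in <- t_in[ok_in]
  y_out <- y_out[ok_out]; t_out <- t_out[ok_out]
  y_all <- c(y_in, y_out); t_all <- c(t_in, t_out)
  unif <- fit_kinetic_model(y_all, t_all, model_id, n_starts = n_starts,
                            rng_seed = rng_seed, floor = floor)
  fin <- fit_kinetic_model(y_in, t_in, model_id, n_starts = n_starts,
                           rng_seed = child_seed(rng_seed, 1), floor = floor)
  fout <- fit_kinetic_model(y_out, t_out, model_id, n_starts = n_starts,
                            rng_seed = child_seed(rng_seed, 2), floor = floor)
  out <- list(uniform_fit = unif, inside_fit = fin, outside_fit = fout,
              effect_size = trajectory_effect_size(y_in, y_out))
  if (!unif$fitted || !fin$fitted || !fout$fitted) {
    out[c("rss_specific", "r2_specific", "lrt_statistic", "df", "p_value")] <-
      list(NA_real_, NA_real_, NA_real_, NA_integer_, NA_real_)
    out$unfit <- TRUE
    return(out)
  }
  rss_s <- fin$rss + fout$rss
  n <- unif$n
  df <- unif$p
  stat <- if (rss_s == 0 && unif$rss == 0) 0 else n * log(unif$rss / rss_s)
  if (is.nan(stat) || stat < 0) stat <- 0
  tss <- sum((y_all - mean(y_all))^2)
  out$rss_specific <- rss_s
  out$r2_specific <- if (tss > 0) 1 - rss_s / tss else if (rss_s <= 1e-12) 1 else 0
  out$lrt_statistic <- stat
  out$df <- df
  out$p_value <- pchisq(stat, df = df, lower.tail = FALSE)
  out$unfit <- FALSE
  out
}

#' Mean fold-change over the three most different bins
#'
#' Identifies the three bins with maximal absolute log2 difference between
#' the inside and outside profiles and returns the mean of the linear
#' fold-changes inside/outside over those bins.
#'
#' @param inside,outside per-bin log2 values (matched bins; `NA` allowed).
#' @return the mean linear fold-change, or `NA` with fewer than 3 shared
#'   bins.
#' @export
trajectory_effect_size <- function(inside, outside) {
  n <- min(length(inside), length(outside))
  inside <- inside[seq_len(n)]; outside <- outside[seq_len(n)]
  ok <- is.finite(inside) & is.finite(outside)
  if (sum(ok) < 3) return(NA_real_)
  d <- inside[ok] - outside[ok]
  top <- order(abs(d), decreasing = TRUE)[1:3]
  mean(2^d[top])
}

#' Call trajectory-specific regulation
#'
#' A (gene, trajectory, component) record is called specific only when the
#' multiplicity-adjusted LRT p-value is below `p_threshold`, the specific
#' fit explains the data well (R-squared above `r2_threshold`), and the
#' effect size lies outside `effect_bounds` (direction taken from the
#' effect relative to 1). Everything else retains the uniform model.
#'
#' @param records data.frame with columns `p_value`, `r2_specific`,
#'   `effect_size` (as from [fit_trajectory_models()]).
#' @param p_threshold adjusted-p threshold (default 0.01).
#' @param r2_threshold specific-fit R-squared threshold (default 0.8).
#' @param effect_bounds uniform band of fold-changes (default `c(0.5, 2)`).
#' @param adjust multiple-testing correction over the record family
#'   (default Benjamini-Hochberg; `"bonferroni"` available).
#' @return `records` with added `p_adjusted` and
#'   `call` in `{uniform, specific_up, specific_down}`.
#' @export
call_trajectory_specific <- function(records, p_threshold = 0.01,
                                     r2_threshold = 0.8,
                                     effect_bounds = c(0.5, 2),
                                     adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  records$p_adjusted <- p.adjust(records$p_value, method = adjust)
  pass <- !is.na(records$p_adjusted) & records$p_adjusted < p_threshold &
    !is.na(records$r2_specific) & records$r2_specific > r2_threshold &
    !is.na(records$effect_size) &
    (records$effect_size > effect_bounds[2] | records$effect_size < effect_bounds[1])
  records$call <- ifelse(!pass, "uniform",
                         ifelse(records$effect_size > 1, "specific_up",
                                "specific_down"))
  records
}

#' Test every gene of a trajectory for specific regulation
#'
#' Convenience wrapper running [fit_trajectory_models()] on the inside and
#' outside binned profiles of each gene. Genes are pre-filtered to those
#' with adequate expression on both sides (mean log2 above `min_mean_expr`
#' in at least `min_bins` bins).
#'
#' @param profiles list with `inside`/`outside` `binned_profile`s (see
#'   [trajectory_binned_profiles()]).
#' @param component `"maternal"` or `"zygotic"`.
#' @param model_id kinetic model; defaults to the component's dynamic model
#'   (`M_decay` or `Z_linear`).
#' @param min_mean_expr,min_bins expression pre-filter (defaults -2 and 6).
#' @param n_starts,rng_seed,floor passed to the fitter.
#' @return data.frame, one row per tested gene, ready for
#'   [call_trajectory_specific()].
#' @export
test_trajectory_genes <- function(profiles, component = c("maternal", "zygotic"),
                                  model_id = NULL, min_mean_expr = -2,
                                  min_bins = 6, n_starts = 100, rng_seed = 1,
                                  floor = -4) {
  component <- match.arg(component)
  model_id <- model_id %||% if (component == "maternal") "M_decay" else "Z_linear"
  yin <- profiles$inside[[component]]
  yout <- profiles$outside[[component]]
  t_in <- profiles$inside$centers
  t_out <- profiles$outside$centers
  ok <- vapply(seq_len(nrow(yin)), function(i) {
    sum(is.finite(yin[i, ]) & yin[i, ] > min_mean_expr) >= min_bins &&
      sum(is.finite(yout[i, ]) & yout[i, ] > min_mean_expr) >= min_bins
  }, logical(1))
  genes <- rownames(yin)[ok]
  rows <- lapply(which(ok), function(i) {
    r <- fit_trajectory_models(yin[i, ], t_in, yout[i, ], t_out, model_id,
                               n_starts = n_starts,
                               rng_seed = child_seed(rng_seed, i),
                               floor = floor)
    data.frame(gene = rownames(yin)[i], component = component,
               model_id = model_id, lrt_statistic = r$lrt_statistic,
               df = r$df, p_value = r$p_value, r2_specific = r$r2_specific,
               effect_size = r$effect_size, unfit = r$unfit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
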