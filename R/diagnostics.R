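## Replicate-derived noise calibration, goodness-of-fit testing, and the
## parameter-recovery simulation study.

#' Construct an expression-group noise model
#'
#' Maps a gene's mean log2 expression to a per-group noise SD through
#' quantile-group boundaries. Group 1 holds the lowest-expression genes.
#'
#' @param sigma per-group noise SD (log2 units), lowest expression first.
#' @param breaks interior group boundaries on mean log2 expression
#'   (`length(sigma) - 1` values, increasing).
#' @param component `"maternal"` or `"zygotic"`.
#' @return a `sigma_model`.
#' @export
sigma_model <- function(sigma, breaks, component = c("maternal", "zygotic")) {
  component <- match.arg(component)
  stopifnot(all(sigma >= 0), length(breaks) == length(sigma) - 1,
            !is.unsorted(breaks))
  structure(list(sigma = sigma, breaks = breaks, component = component,
                 n_groups = length(sigma)),
            class = "sigma_model")
}

#' Constant-noise model
#' @param sigma single SD applied to every gene.
#' @param component component label.
#' @return a `sigma_model` with one group.
#' @export
uniform_sigma_model <- function(sigma, component = "maternal") {
  sigma_model(sigma, numeric(0), component)
}

#' Look up the noise SD for genes by mean expression
#'
#' @param model a `sigma_model`.
#' @param mean_expr per-gene mean log2 expression.
#' @return per-gene SD.
#' @export
sigma_lookup <- function(model, mean_expr) {
  stopifnot(inherits(model, "sigma_model"))
  model$sigma[findInterval(mean_expr, model$breaks) + 1L]
}

#' Default expression-group noise model
#'
#' A replicate-concordance-shaped default for synthetic data: pseudo-bulk
#' log2 noise decreasing with expression, from ~0.8 for barely detected
#' genes to ~0.15 for abundant ones. Maternal profiles use 6 groups and
#' zygotic 10, mirroring the group counts used when calibrating from real
#' replicates.
#'
#' @param component `"maternal"` or `"zygotic"`.
#' @return a `sigma_model`.
#' @export
default_sigma_model <- function(component = c("maternal", "zygotic")) {
  component <- match.arg(component)
  if (component == "maternal")
    sigma_model(c(0.8, 0.5, 0.35, 0.28, 0.2, 0.15),
                breaks = c(-2, 0, 2, 4, 6), component = component)
  else
    sigma_model(c(0.9, 0.7, 0.55, 0.45, 0.38, 0.32, 0.27, 0.22, 0.18, 0.15),
                breaks = c(-3, -2, -1, 0, 1, 2, 3, 4, 5), component = component)
}

#' Estimate expression-group noise from two replicates
#'
#' Genes are grouped by quantiles of their mean expression across both
#' replicates (6 groups for the maternal component, 10 for the zygotic, by
#' default), and each group's SD is the root mean square of the paired
#' replicate differences over all (gene, sample) terms in the group.
#'
#' @param triplet_a,triplet_b `expression_triplet`s over matched samples
#'   from two replicates.
#' @param component which component matrix to calibrate on.
#' @param n_groups number of quantile groups (default 6 maternal,
#'   10 zygotic).
#' @return a `sigma_model` whose breaks are the observed quantile edges.
#' @export
estimate_replicate_sigma <- function(triplet_a, triplet_b,
                                     component = c("maternal", "zygotic"),
                                     n_groups = NULL) {
  component <- match.arg(component)
  n_groups <- n_groups %||% if (component == "maternal") 6L else 10L
  a <- triplet_a[[component]]; b <- triplet_b[[component]]
  if (is.null(a) || is.null(b)) stop("missing replicate component matrix", call. = FALSE)
  stopifnot(all(dim(a) == dim(b)))
  if (nrow(a) < n_groups) stop("fewer genes than groups", call. = FALSE)
  mean_expr <- rowMeans(cbind(a, b), na.rm = TRUE)
  edges <- quantile(mean_expr, probs = seq(0, 1, length.out = n_groups + 1),
                    na.rm = TRUE, names = FALSE)
  breaks <- edges[-c(1, n_groups + 1)]
  grp <- findInterval(mean_expr, breaks) + 1L
  d2 <- (a - b)^2
  sig <- vapply(seq_len(n_groups), function(g) {
    v <- d2[grp == g, , drop = FALSE]
    v <- v[is.finite(v)]
    if (!length(v)) return(0)
    sqrt(sum(v) / length(v))
  }, numeric(1))
  sigma_model(sig, breaks, component)
}

#' Chi-square goodness-of-fit test of model predictions
#'
#' Computes `S = sum(((observed - predicted) / sigma)^2)` over observations
#' with reliable expression (`observed > floor`) and compares it to a
#' chi-square with degrees of freedom equal to the number of terms
#' included. A fit is retained when `p > retain_alpha`.
#'
#' @param observed,predicted numeric vectors, or gene x observation
#'   matrices.
#' @param sigma per-gene noise SD (scalar or one per gene/row).
#' @param floor reliability threshold; observations at or below it are
#'   excluded (default -4). Use `-Inf` to include everything.
#' @param retain_alpha retention level (default 0.05).
#' @return data.frame with `S_hat`, `dof`, `p_value`, `retained`.
#' @export
goodness_of_fit <- function(observed, predicted, sigma, floor = -4,
                            retain_alpha = 0.05) {
  if (is.null(dim(observed))) observed <- matrix(observed, nrow = 1)
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  stopifnot(all(dim(observed) == dim(predicted)))
  ng <- nrow(observed)
  sigma <- rep_len(sigma, ng)
  use <- !is.na(observed) & !is.na(predicted) & observed > floor
  resid2 <- (observed - predicted)^2
  resid2[!use] <- 0
  dof <- rowSums(use)
  S <- rowSums(resid2) / sigma^2
  ## degenerate noise: zero sigma retains only perfect fits
  zero_sig <- sigma == 0
  S[zero_sig] <- ifelse(rowSums(resid2)[zero_sig] > 0, Inf, 0)
  p <- ifelse(dof >= 1, pchisq(S, df = pmax(dof, 1), lower.tail = FALSE), NA_real_)
  out <- data.frame(S_hat = S, dof = dof, p_value = p,
                    retained = !is.na(p) & p > retain_alpha)
  rn <- rownames(observed)
  if (!is.null(rn) && !anyDuplicated(rn)) rownames(out) <- rn
  out
}

#' Stage pseudotime anchors for stage-level goodness-of-fit
#'
#' Developmental stages mapped onto the pseudo-minute axis: dome at 260,
#' 30% epiboly at 310, 50% epiboly at 340.
#' @return named numeric vector.
#' @export
stage_pseudotimes <- function() c(dome = 260, epb30 = 310, epb50 = 340)

#' Parameter-recovery simulation study
#'
#' For every parameter set of `grid`, generates noiseless binned profiles
#' from the model, adds Normal noise at each multiplier of the gene's
#' expression-group SD, refits the generating model, and scores parameter
#' recovery plus a goodness-of-fit of the fitted curve against the
#' noiseless truth (at the unmultiplied group SD).
#'
#' @param grid a `simulation_grid` (see [build_parameter_grid()]) whose
#'   columns are the parameters of `model_id`.
#' @param model_id generating (and fitted) model, e.g. `"M_decay"`.
#' @param sigma_model noise model giving each simulated gene its SD from
#'   its mean noiseless log2 expression.
#' @param replicates noisy replicates per grid point and multiplier
#'   (default 100).
#' @param noise_multipliers SD multipliers (default `c(0.5, 1, 1.5)`).
#' @param bins bin centers, pseudo-minutes.
#' @param n_starts multistart budget per fit.
#' @param rng_seed integer seed.
#' @param floor log2 floor.
#' @return data.frame, one row per (grid point, multiplier, replicate),
#'   with true and estimated parameters, absolute relative errors, onset
#'   error, and goodness-of-fit retention.
#' @export
run_simulation_study <- function(grid, model_id, sigma_model = default_sigma_model(
                                   model_component(model_id)),
                                 replicates = 100,
                                 noise_multipliers = c(0.5, 1, 1.5),
                                 bins = bin_spec()$centers, n_starts = 50,
                                 rng_seed = 1, floor = -4) {
  stopifnot(inherits(grid, "simulation_grid"))
  nm <- model_param_names(model_id)
  if (!all(nm %in% colnames(grid)))
    stop("grid must provide columns: ", paste(nm, collapse = ", "), call. = FALSE)
  rate_par <- intersect(c("beta", "alpha"), nm)[1]
  out <- vector("list", nrow(grid) * length(noise_multipliers))
  k <- 0
  for (i in seq_len(nrow(grid))) {
    pars <- as.list(grid[i, nm, drop = FALSE])
    truth_curve <- model_curve(model_id, pars, bins, floor = floor)
    sig <- sigma_lookup(sigma_model, mean(truth_curve))
    for (m in noise_multipliers) {
      seeds <- vapply(seq_len(replicates), function(r)
        child_seed(rng_seed, (i * 1000 + k) * replicates + r), integer(1))
      reps <- lapply(seq_len(replicates), function(r) {
        y <- with_seed(seeds[r],
                       pmax(truth_curve + rnorm(length(bins), 0, m * sig), floor))
        fit <- fit_kinetic_model(y, bins, model_id, n_starts = n_starts,
                                 rng_seed = child_seed(seeds[r], 7), floor = floor)
        if (!fit$fitted) {
          est <- setNames(rep(NA_real_, length(nm)), nm)
          gof <- data.frame(p_value = NA_real_, retained = NA)
        } else {
          est <- unlist(fit$params)[nm]
          gof <- goodness_of_fit(truth_curve, fit$fitted_values, sig,
                                 floor = floor)
        }
        row <- data.frame(grid_point = i, multiplier = m, replicate = r)
        for (p in nm) {
          row[[paste0("true_", p)]] <- pars[[p]]
          row[[paste0("est_", p)]] <- est[[p]]
        }
        row$rate_rel_err <- abs(est[[rate_par]] - pars[[rate_par]]) / pars[[rate_par]]
        row$onset_abs_err <- abs(est[["d"]] - pars[["d"]])
        row$gof_p <- gof$p_value
        row$retained <- gof$retained
        row
      })
      k <- k + 1
      out[[k]] <- do.call(rbind, reps)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("recovery_report", class(res))
  res
}

#' Summarize a recovery report
#'
#' Median absolute relative rate error, median onset error, and retention
#' fraction per noise multiplier.
#'
#' @param object a `recovery_report` from [run_simulation_study()].
#' @param ... unused.
#' @return data.frame per multiplier.
#' @export
summary.recovery_report <- function(object, ...) {
  mult <- sort(unique(object$multiplier))
  do.call(rbind, lapply(mult, function(m) {
    d <- object[object$multiplier == m, ]
    data.frame(multiplier = m,
               median_rate_rel_err = median(d$rate_rel_err, na.rm = TRUE),
               median_onset_abs_err = median(d$onset_abs_err, na.rm = TRUE),
               retained_fraction = mean(d$retained, na.rm = TRUE),
               n_fits = nrow(d))
  }))
}
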