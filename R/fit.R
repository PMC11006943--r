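## Multistart bounded least-squares fitting of the kinetic models on the
## log2 scale, likelihood-ratio model selection, and gene classification.

## run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

new_model_fit <- function(model_id, params, y, t, floor, converged = TRUE) {
  n <- length(y)
  p <- length(model_param_names(model_id))
  pred <- model_curve(model_id, params, t, floor = floor)
  rss <- sum((y - pred)^2)
  sigma_ml <- sqrt(rss / n)
  loglik <- if (rss > 0) -n / 2 * log(2 * pi * sigma_ml^2) - n / 2 else Inf
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else if (rss <= 1e-12) 1 else 0
  structure(list(
    model_id = model_id, params = params, n = n, p = p,
    rss = rss, sigma_ml = sigma_ml, loglik = loglik, r_squared = r2,
    fitted_values = pred, times = t, observed = y,
    fitted = TRUE, converged = converged, floor = floor),
    class = "model_fit")
}

unfit_marker <- function(model_id, n, reason) {
  structure(list(model_id = model_id, params = NULL, n = n,
                 p = length(model_param_names(model_id)),
                 rss = NA_real_, sigma_ml = NA_real_, loglik = NA_real_,
                 r_squared = NA_real_, fitted = FALSE, converged = FALSE,
                 reason = reason),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  if (!x$fitted) {
    cat("<model_fit>", x$model_id, "UNFIT (", x$reason, ")\n")
    return(invisible(x))
  }
  cat("<model_fit>", x$model_id, " n =", x$n, " p =", x$p,
      " rss =", signif(x$rss, 4), " R2 =", signif(x$r_squared, 4), "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), signif(unlist(x$params), 4),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

## parameter transforms: rates on log scale, x0 on log2 scale, onsets linear
par_transform <- function(model_id, params) {
  nm <- model_param_names(model_id)
  out <- vapply(nm, function(p) {
    v <- params[[p]]
    if (p == "x0") log2(v) else if (p == "d") v else log(v)
  }, numeric(1))
  setNames(out, nm)
}

par_untransform <- function(model_id, tpar) {
  nm <- model_param_names(model_id)
  out <- lapply(nm, function(p) {
    v <- tpar[[p]]
    if (p == "x0") 2^v else if (p == "d") v else exp(v)
  })
  setNames(out, nm)
}

## data-driven starts: profile the onset d over candidate times and solve
## the conditionally linear subproblem at each, so a start in the global
## basin is always among the candidates
heuristic_starts <- function(model_id, y, t, bounds, floor) {
  up <- function(p, v) clamp(v, bounds[[p]][1], bounds[[p]][2])
  l2e <- log2(exp(1))
  cand_d <- up("d", unique(c(min(t) - 20, t, mean(range(t)))))
  if (model_id == "M_decay") {
    sts <- lapply(cand_d, function(d) {
      x <- pmax(0, t - d) * l2e
      if (sum(x > 0) >= 2 && var(x) > 0) {
        co <- stats::lm.fit(cbind(1, -x), y)$coefficients
        list(x0 = up("x0", 2^co[1]), beta = up("beta", max(co[2], 1e-4)),
             d = d)
      } else {
        list(x0 = up("x0", 2^mean(y)), beta = up("beta", 1e-3), d = d)
      }
    })
    ## the flat constant solution is nested at d = upper bound; include it
    ## so the richer model never scores worse than the constant fit
    sts <- c(sts, list(list(x0 = up("x0", 2^mean(y)), beta = bounds$beta[1],
                            d = bounds$d[2])))
  } else {
    sts <- lapply(cand_d, function(d) {
      pos <- t > d & y > floor + 0.25
      la <- if (sum(pos) >= 1) mean(y[pos] - log2(t[pos] - d)) / l2e
            else log(sqrt(prod(bounds$alpha)))
      st <- list(alpha = up("alpha", exp(la)), d = d)
      if (model_id == "Z_sat") st$beta_z <- up("beta_z", 0.01)
      st
    })
    if (model_id == "Z_sat") {
      ## saturating variants: a visible plateau pins alpha / beta_z at the
      ## late-bin level; beta_z at its lower bound recovers the nested
      ## near-linear regime
      plateau <- 2^mean(tail(sort(y), 3))
      sat <- lapply(cand_d, function(d) {
        bz <- 0.05
        list(alpha = up("alpha", plateau * bz), d = d,
             beta_z = up("beta_z", bz))
      })
      lin <- lapply(sts, function(st) {
        st$beta_z <- bounds$beta_z[1]
        st
      })
      sts <- c(sts, sat, lin)
    }
  }
  ## keep the most promising candidates by their residual sum of squares
  rss <- vapply(sts, function(p)
    sum((y - model_curve(model_id, p, t, floor = floor))^2), numeric(1))
  sts[order(rss)][seq_len(min(6L, length(sts)))]
}

random_starts <- function(model_id, n, bounds) {
  nm <- model_param_names(model_id)
  draws <- lapply(nm, function(p) {
    b <- bounds[[p]]
    if (p == "d") runif(n, b[1], b[2])
    else if (p == "x0") 2^runif(n, log2(b[1]), log2(b[2]))
    else exp(runif(n, log(b[1]), log(b[2])))
  })
  names(draws) <- nm
  draws
}

#' Fit a kinetic model by multistart bounded least squares
#'
#' Fits the model curve (log2 scale) to per-bin log2 observations by
#' minimizing the residual sum of squares with `nlminb` under box
#' constraints, restarting from `n_starts` start points (one data-driven
#' start plus random starts drawn log-uniformly for rates and uniformly for
#' onsets) and retaining the best optimum. Null models have no parameters;
#' the constant model is solved in closed form.
#'
#' @param y log2 observations (floored at `floor` before fitting).
#' @param t observation times, pseudo-minutes.
#' @param model_id one of `M_null`, `M_const`, `M_decay`, `Z_null`,
#'   `Z_linear`, `Z_sat`.
#' @param bounds named list of `c(lower, upper)` per parameter
#'   (default [default_bounds()]).
#' @param n_starts number of start points for the nonlinear models.
#' @param rng_seed integer seed making the fit deterministic.
#' @param floor log2 expression floor (default -4).
#' @return a `model_fit` with parameters (natural scale), `rss`,
#'   `sigma_ml = sqrt(rss/n)`, log-likelihood, and R-squared; an unfit
#'   marker if there are fewer than p+1 usable observations or no start
#'   converges.
#' @export
fit_kinetic_model <- function(y, t, model_id,
                              bounds = default_bounds(model_id),
                              n_starts = 500, rng_seed = 1, floor = -4) {
  stopifnot(length(y) == length(t))
  keep <- is.finite(y) & is.finite(t)
  y <- pmax(y[keep], floor); t <- t[keep]
  p <- length(model_param_names(model_id))
  if (length(y) < p + 1)
    return(unfit_marker(model_id, length(y), "fewer observations than parameters + 1"))

  if (p == 0)
    return(new_model_fit(model_id, list(), y, t, floor))
  if (model_id == "M_const") {
    x0 <- clamp(2^mean(y), bounds$x0[1], bounds$x0[2])
    return(new_model_fit(model_id, list(x0 = x0), y, t, floor))
  }

  nm <- model_param_names(model_id)
  lower <- par_transform(model_id, lapply(bounds, `[`, 1)[nm])
  upper <- par_transform(model_id, lapply(bounds, `[`, 2)[nm])
  l2e <- log2(exp(1))
  ## objectives inlined on the transformed scale for speed
  obj <- switch(model_id,
    M_decay = function(tp) {
      r <- y - (tp[1] - exp(tp[2]) * pmax(0, t - tp[3]) * l2e)
      sum(r * r)
    },
    Z_linear = function(tp) {
      dt <- t - tp[2]
      mu <- rep(floor, length(t))
      pos <- dt > 0
      mu[pos] <- tp[1] * l2e + log2(dt[pos])
      r <- y - pmax(mu, floor)
      sum(r * r)
    },
    Z_sat = function(tp) {
      dt <- t - tp[2]
      bz <- exp(tp[3])
      mu <- rep(floor, length(t))
      pos <- dt > 0
      mu[pos] <- (tp[1] - tp[3]) * l2e + log2(1 - exp(-bz * dt[pos]))
      r <- y - pmax(mu, floor)
      sum(r * r)
    })

  with_seed(rng_seed, {
    hstarts <- heuristic_starts(model_id, y, t, bounds, floor)
    n_h <- length(hstarts)
    starts <- random_starts(model_id, max(n_starts - n_h, 0L), bounds)
    best <- NULL
    for (i in seq_len(max(n_starts, n_h))) {
      st <- if (i <= n_h) hstarts[[i]]
            else setNames(lapply(starts, `[`, i - n_h), nm)
      tp0 <- par_transform(model_id, st)
      res <- tryCatch(
        nlminb(tp0, obj, lower = lower, upper = upper,
               control = list(iter.max = 300)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$objective < best$objective))
        best <- res
    }
    if (is.null(best))
      return(unfit_marker(model_id, length(y), "optimizer failed on all starts"))
    pars <- par_untransform(model_id, setNames(as.list(best$par), nm))
    new_model_fit(model_id, pars, y, t, floor, converged = best$convergence == 0)
  })
}

#' Likelihood-ratio test between nested kinetic model fits
#'
#' For least-squares fits with the maximum-likelihood noise estimate
#' `sigma_ml = sqrt(rss/n)`, twice the log-likelihood difference reduces to
#' `n * ln(rss_null / rss_alt)`; it is compared to a chi-square with
#' `p_alt - p_null` degrees of freedom.
#'
#' @param fit_null,fit_alt `model_fit` objects on the same observations,
#'   with `fit_alt` the richer model.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "model_fit"), inherits(fit_alt, "model_fit"))
  if (fit_alt$p <= fit_null$p) stop("models are not nested (p_alt must exceed p_null)", call. = FALSE)
  if (fit_null$n != fit_alt$n) stop("fits use different observation counts", call. = FALSE)
  n <- fit_null$n
  df <- fit_alt$p - fit_null$p
  stat <- if (fit_alt$rss == 0 && fit_null$rss == 0) 0
          else n * log(fit_null$rss / fit_alt$rss)
  if (is.nan(stat)) stat <- 0
  if (stat < 0) {
    ## a slightly larger alternative rss is legitimate when the richer
    ## model reaches the null only at a parameter bound (the saturating
    ## model with beta_z at its lower limit deviates from linear by up to
    ## ~0.01 log2 per bin); warn only for material exceedance, which
    ## indicates optimizer failure
    if (fit_alt$rss > fit_null$rss * 1.05 + 1e-8)
      warning("alternative fit has larger rss than null; statistic clamped at 0")
    stat <- 0
  }
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Select among nested kinetic models for one gene profile
#'
#' Implements the nested chain NULL (constant floor, 0 parameters) in F1
#' (maternal: constant level; zygotic: linear accumulation) in F2 (maternal:
#' delayed exponential decay; zygotic: saturating accumulation). Genes with
#' more than `low_expr_max_bins` bins below `low_expr_threshold` are
#' assigned the null model outright. Otherwise F1 and F2 are fit and the
#' richer model is accepted only when the likelihood-ratio test rejects at
#' `alpha_level`.
#'
#' @param y per-bin log2 values (floored at `floor`).
#' @param t bin times, pseudo-minutes.
#' @param component `"maternal"` or `"zygotic"`.
#' @param alpha_level LRT acceptance level (default 0.05).
#' @param low_expr_threshold,low_expr_max_bins the low-expression null rule:
#'   more than `low_expr_max_bins` bins below `low_expr_threshold` selects
#'   the null model (defaults -3 and 4).
#' @param bounds,n_starts,rng_seed,floor passed to [fit_kinetic_model()].
#' @return a `model_selection`: list with `selected` (`model_fit`), all
#'   `fits`, the LRT `p_values`, and the decision `rule`.
#' @export
select_nested_model <- function(y, t, component = c("maternal", "zygotic"),
                                alpha_level = 0.05,
                                low_expr_threshold = -3, low_expr_max_bins = 4,
                                bounds = NULL, n_starts = 500, rng_seed = 1,
                                floor = -4) {
  component <- match.arg(component)
  ids <- if (component == "maternal") c("M_null", "M_const", "M_decay")
         else c("Z_null", "Z_linear", "Z_sat")
  keep <- is.finite(y)
  y <- pmax(y[keep], floor); t <- t[keep]

  fit0 <- fit_kinetic_model(y, t, ids[1], floor = floor)
  sel <- structure(list(component = component, selected = fit0,
                        fits = list(fit0), p_values = c(NA_real_, NA_real_),
                        rule = "low_expression"),
                   class = "model_selection")
  names(sel$fits) <- ids[1]
  if (sum(y < low_expr_threshold) > low_expr_max_bins) return(sel)

  b1 <- bounds %||% default_bounds(ids[2])
  b2 <- bounds %||% default_bounds(ids[3])
  fit1 <- fit_kinetic_model(y, t, ids[2], bounds = b1[model_param_names(ids[2])],
                            n_starts = n_starts, rng_seed = rng_seed, floor = floor)
  fit2 <- fit_kinetic_model(y, t, ids[3], bounds = b2[model_param_names(ids[3])],
                            n_starts = n_starts, rng_seed = child_seed(rng_seed, 1),
                            floor = floor)
  sel$fits <- setNames(list(fit0, fit1, fit2), ids)
  sel$rule <- "lrt"
  p1 <- if (fit1$fitted) likelihood_ratio_test(fit0, fit1)$p_value else NA_real_
  sel$p_values[1] <- p1
  if (is.na(p1) || p1 >= alpha_level) {
    sel$selected <- fit0
    return(sel)
  }
  sel$selected <- fit1
  p2 <- if (fit2$fitted) likelihood_ratio_test(fit1, fit2)$p_value else NA_real_
  sel$p_values[2] <- p2
  if (!is.na(p2) && p2 < alpha_level) sel$selected <- fit2
  sel
}

#' Classify a gene and assign its kinetic group
#'
#' The gene class records which components carry a non-null selected model
#' (`maternal_only`, `zygotic_only`, `maternal_zygotic`, or `unfit` when
#' neither fits). For maternal-zygotic genes with an exponential-decay
#' maternal model and an accumulation-rate estimate, genes are grouped by
#' fast/slow maternal half-life and fast/slow zygotic accumulation:
#' A = fast decay + fast accumulation (replacement), B = fast decay + slow
#' accumulation (net decrease), C = slow decay + slow accumulation, D = slow
#' decay + fast accumulation (net increase). Genes inside the excluded
#' middle bands are `unassigned`.
#'
#' @param maternal,zygotic `model_selection` objects (or `NULL`).
#' @param half_life_bounds fast/slow half-life cutoffs, pseudo-minutes
#'   (default `c(20, 45)`: fast < 20, slow > 45).
#' @param log2_alpha_bounds slow/fast log2 accumulation cutoffs (default
#'   `c(-12, -11)`: slow < -12, fast > -11).
#' @return list with `gene_class`, `half_life_pseudo_min`, `group`, and the
#'   selected model ids.
#' @export
classify_and_group <- function(maternal = NULL, zygotic = NULL,
                               half_life_bounds = c(20, 45),
                               log2_alpha_bounds = c(-12, -11)) {
  m_id <- if (!is.null(maternal)) maternal$selected$model_id else "M_null"
  z_id <- if (!is.null(zygotic)) zygotic$selected$model_id else "Z_null"
  m_on <- m_id != "M_null"
  z_on <- z_id != "Z_null"
  gene_class <- if (m_on && z_on) "maternal_zygotic"
                else if (m_on) "maternal_only"
                else if (z_on) "zygotic_only"
                else "unfit"
  half_life <- NA_real_
  if (m_id == "M_decay")
    half_life <- log(2) / maternal$selected$params$beta
  group <- "unassigned"
  if (gene_class == "maternal_zygotic" && is.finite(half_life) &&
      z_id %in% c("Z_linear", "Z_sat")) {
    l2a <- log2(zygotic$selected$params$alpha)
    fast_hl <- half_life < half_life_bounds[1]
    slow_hl <- half_life > half_life_bounds[2]
    slow_a <- l2a < log2_alpha_bounds[1]
    fast_a <- l2a > log2_alpha_bounds[2]
    if (fast_hl && fast_a) group <- "A"
    else if (fast_hl && slow_a) group <- "B"
    else if (slow_hl && slow_a) group <- "C"
    else if (slow_hl && fast_a) group <- "D"
  }
  list(gene_class = gene_class, half_life_pseudo_min = half_life,
       group = group, maternal_model = m_id, zygotic_model = z_id)
}

#' Fit and classify kinetics for every gene of a binned profile
#'
#' Runs [select_nested_model()] on the maternal and zygotic components of
#' each gene and [classify_and_group()] on the results.
#'
#' @param profile a `binned_profile` (see [binned_profile()]).
#' @param alpha_level,n_starts,rng_seed,floor passed to the selector.
#' @param half_life_bounds,log2_alpha_bounds passed to
#'   [classify_and_group()].
#' @return data.frame, one row per gene, with selected models, parameters,
#'   half-life, fit statistics, LRT p-values, class, and group.
#' @export
fit_gene_kinetics <- function(profile, alpha_level = 0.05, n_starts = 100,
                              rng_seed = 1, floor = -4,
                              half_life_bounds = c(20, 45),
                              log2_alpha_bounds = c(-12, -11)) {
  genes <- rownames(profile$maternal)
  t <- profile$centers
  rows <- lapply(seq_along(genes), function(i) {
    ms <- select_nested_model(profile$maternal[i, ], t, "maternal",
                              alpha_level = alpha_level, n_starts = n_starts,
                              rng_seed = child_seed(rng_seed, 2 * i), floor = floor)
    zs <- select_nested_model(profile$zygotic[i, ], t, "zygotic",
                              alpha_level = alpha_level, n_starts = n_starts,
                              rng_seed = child_seed(rng_seed, 2 * i + 1), floor = floor)
    cl <- classify_and_group(ms, zs, half_life_bounds, log2_alpha_bounds)
    mp <- ms$selected$params; zp <- zs$selected$params
    data.frame(
      gene = genes[i],
      maternal_model = cl$maternal_model,
      x0 = mp$x0 %||% NA_real_, beta = mp$beta %||% NA_real_,
      d_m = mp$d %||% NA_real_,
      half_life_pseudo_min = cl$half_life_pseudo_min,
      maternal_rss = ms$selected$rss, maternal_sigma_ml = ms$selected$sigma_ml,
      maternal_r2 = ms$selected$r_squared,
      p_maternal_f1 = ms$p_values[1], p_maternal_f2 = ms$p_values[2],
      zygotic_model = cl$zygotic_model,
      alpha = zp$alpha %||% NA_real_, d_z = zp$d %||% NA_real_,
      beta_z = zp$beta_z %||% NA_real_,
      zygotic_rss = zs$selected$rss, zygotic_sigma_ml = zs$selected$sigma_ml,
      zygotic_r2 = zs$selected$r_squared,
      p_zygotic_f1 = zs$p_values[1], p_zygotic_f2 = zs$p_values[2],
      gene_class = cl$gene_class, group = cl$group,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
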