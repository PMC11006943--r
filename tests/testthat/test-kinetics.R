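test_that("model curves obey their analytic identities", {
  # one 20-minute half-life after onset loses exactly 1 log2 unit
  expect_equal(evaluate_maternal(list(x0 = 1, beta = log(2) / 20, d = 240), 260), -1)
  # continuity at onset and flat plateau before it
  p <- list(x0 = 2^5, beta = 0.02, d = 300)
  expect_equal(evaluate_maternal(p, 300), 5)
  expect_equal(evaluate_maternal(p, c(240, 260, 299)), rep(5, 3))
  # linear accumulation: alpha * (t - d) = 1 -> log2 = 0
  expect_equal(evaluate_zygotic(list(alpha = 0.01, d = 240), 340), 0)
  # saturating model plateaus at alpha / beta_z
  zp <- list(alpha = 0.04, d = 250, beta_z = 0.05)
  expect_equal(evaluate_zygotic(zp, 1e6), log2(0.04 / 0.05), tolerance = 1e-9)
  # just after onset the curve is clamped at the floor
  expect_equal(evaluate_zygotic(list(alpha = 0.01, d = 300), 300 + 1e-9), -4)
})

test_that("noiseless decay data is recovered to high relative accuracy", {
  t <- default_centers()
  truth <- list(x0 = 2^7, beta = log(2) / 40, d = 280)
  y <- evaluate_maternal(truth, t)
  fit <- fit_kinetic_model(y, t, "M_decay", n_starts = 60, rng_seed = 3)
  # independent dense grid-search oracle over (beta, d), x0 profiled
  l2e <- log2(exp(1))
  oracle <- expand.grid(beta = log(2) / seq(20, 80, by = 0.5),
                        d = seq(260, 300, by = 0.25))
  rss <- vapply(seq_len(nrow(oracle)), function(i) {
    x <- pmax(0, t - oracle$d[i]) * l2e * oracle$beta[i]
    a <- mean(y + x)
    sum((y - (a - x))^2)
  }, numeric(1))
  best <- oracle[which.min(rss), ]
  expect_lt(abs(best$beta - truth$beta) / truth$beta, 0.01)  # oracle sanity
  for (p in names(truth))
    expect_lt(abs(fit$params[[p]] - truth[[p]]) / truth[[p]], 1e-3)
  expect_lt(fit$rss, 1e-12)
  # determinism under a fixed seed
  fit2 <- fit_kinetic_model(y, t, "M_decay", n_starts = 60, rng_seed = 3)
  expect_identical(fit$params, fit2$params)
})

test_that("flat profiles yield the constant model with exact fit", {
  t <- default_centers()
  fit <- fit_kinetic_model(rep(3, 11), t, "M_const")
  expect_equal(fit$params$x0, 2^3)
  expect_equal(fit$rss, 0)
  expect_equal(fit$r_squared, 1)  # zero-variance observations, perfect fit
  expect_equal(fit$sigma_ml, 0)
  # too few observations produce an unfit marker
  expect_false(fit_kinetic_model(c(1, 2), t[1:2], "M_decay")$fitted)
})

test_that("likelihood-ratio test matches its closed form", {
  t <- default_centers()
  y <- rep(2, 11)
  f0 <- fit_kinetic_model(y, t, "M_null")
  f1 <- fit_kinetic_model(y, t, "M_const")
  # identical rss -> statistic 0, p = 1 (df 2 case via params count)
  same <- suppressWarnings(
    likelihood_ratio_test(f1, fit_kinetic_model(y, t, "M_decay",
                                                n_starts = 20, rng_seed = 1)))
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1, tolerance = 1e-5)
  # n = 11, rss halved, df = 1: statistic 11 ln 2, p ~ 0.0058
  fa <- f0; fa$rss <- 4; fa$p <- 0; fa$n <- 11
  fb <- f1; fb$rss <- 2; fb$p <- 1; fb$n <- 11
  lrt <- likelihood_ratio_test(fa, fb)
  expect_equal(lrt$statistic, 11 * log(2))
  expect_equal(lrt$p_value, 0.00576, tolerance = 1e-3)
  expect_error(likelihood_ratio_test(fb, fa), "nested")
})

test_that("nested selection applies the low-expression rule and nesting holds", {
  t <- default_centers()
  y <- c(rep(-3.5, 5), rep(1, 6))
  sel <- select_nested_model(y, t, "maternal", n_starts = 20, rng_seed = 1)
  expect_equal(sel$selected$model_id, "M_null")
  expect_equal(sel$rule, "low_expression")
  # rss ordering over a batch of noisy decay genes
  set.seed(4)
  for (i in 1:8) {
    yy <- evaluate_maternal(list(x0 = 2^runif(1, 4, 9),
                                 beta = log(2) / runif(1, 15, 120),
                                 d = runif(1, 250, 320)), t) + rnorm(11, 0, 0.2)
    s <- select_nested_model(yy, t, "maternal", n_starts = 40, rng_seed = i)
    rss <- vapply(s$fits, `[[`, numeric(1), "rss")
    expect_true(rss["M_decay"] <= rss["M_const"] + 1e-9)
    expect_true(rss["M_const"] <= rss["M_null"] + 1e-9)
  }
})

test_that("strong curvature selects the saturating zygotic model", {
  t <- default_centers()
  zp <- list(alpha = 0.1, d = 250, beta_z = 0.06)
  set.seed(5)
  y <- evaluate_zygotic(zp, t) + rnorm(11, 0, 0.05)
  sel <- select_nested_model(y, t, "zygotic", n_starts = 60, rng_seed = 2)
  expect_equal(sel$selected$model_id, "Z_sat")
  expect_lt(abs(sel$selected$params$beta_z - zp$beta_z) / zp$beta_z, 0.25)
})

test_that("classification and grouping follow the half-life/accumulation bounds", {
  t <- default_centers()
  mk_sel <- function(model_id, params) {
    f <- mztkin:::new_model_fit(model_id, params,
                                model_curve(model_id, params, t), t, -4)
    structure(list(component = "x", selected = f, fits = list(f),
                   p_values = c(0, 0), rule = "lrt"), class = "model_selection")
  }
  mfast <- mk_sel("M_decay", list(x0 = 2^6, beta = log(2) / 15, d = 260))
  mslow <- mk_sel("M_decay", list(x0 = 2^6, beta = log(2) / 60, d = 260))
  mmid <- mk_sel("M_decay", list(x0 = 2^6, beta = log(2) / 30, d = 260))
  zfast <- mk_sel("Z_linear", list(alpha = 2^-10.5, d = 260))
  # half-life 15 + log2 alpha -10.5 -> A; half-life 60 same alpha -> D
  expect_equal(classify_and_group(mfast, zfast)$group, "A")
  expect_equal(classify_and_group(mslow, zfast)$group, "D")
  # half-life inside the excluded band -> unassigned
  expect_equal(classify_and_group(mmid, zfast)$group, "unassigned")
  # half-life / beta reciprocity is exact
  cg <- classify_and_group(mfast, zfast)
  expect_equal(cg$half_life_pseudo_min * mfast$selected$params$beta, log(2))
  # class bookkeeping
  expect_equal(classify_and_group(mfast, NULL)$gene_class, "maternal_only")
  expect_equal(classify_and_group(NULL, zfast)$gene_class, "zygotic_only")
  expect_equal(classify_and_group(NULL, NULL)$gene_class, "unfit")
})

test_that("null LRT rejection rate is calibrated in the small-p tail", {
  # The decay alternative is boundary-constrained (beta > 0, onset in a
  # box), so the null p-value distribution is a conservative mixture
  # rather than Uniform(0,1); what model selection relies on is the
  # rejection rate at small alpha, which should not exceed nominal and
  # should sit near it at the working level 0.05.
  t <- default_centers()
  set.seed(6)
  ps <- vapply(1:300, function(i) {
    y <- rep(3, 11) + rnorm(11, 0, 0.25)
    f1 <- fit_kinetic_model(y, t, "M_const")
    f2 <- fit_kinetic_model(y, t, "M_decay", n_starts = 40, rng_seed = i)
    likelihood_ratio_test(f1, f2)$p_value
  }, numeric(1))
  rate05 <- mean(ps < 0.05)
  expect_gt(rate05, 0.015)
  expect_lt(rate05, 0.095)
  expect_lte(mean(ps < 0.01), 0.04)
})
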