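## Kinetic model curves for maternal decay and zygotic accumulation, on the
## log2 scale used for fitting. Time is in pseudo-minutes post fertilization.

#' Maternal mRNA decay curve (log2 scale)
#'
#' Exponential decay of pre-existing maternal transcripts with a delayed
#' onset: expression is flat at the initial level `x0` until the degradation
#' onset time `d`, then decays at constant rate `beta`. On the log2 scale the
#' post-onset curve is linear with slope `-beta * log2(e)`.
#'
#' @param params named list or vector with `x0` (initial expression, linear
#'   units), `beta` (decay rate per pseudo-minute, > 0) and `d` (degradation
#'   onset, pseudo-minutes).
#' @param t numeric vector of pseudo-minutes.
#' @return log2 expression at each `t`.
#' @examples
#' evaluate_maternal(list(x0 = 1, beta = log(2) / 20, d = 240), 260)  # -1
#' @export
evaluate_maternal <- function(params, t) {
  x0 <- params[["x0"]]; beta <- params[["beta"]]; d <- params[["d"]]
  log2(x0) - beta * pmax(0, t - d) * log2(exp(1))
}

#' Zygotic mRNA accumulation curve (log2 scale)
#'
#' Newly transcribed mRNA accumulating from transcription onset `d` at a
#' constant rate `alpha` (transcripts per pseudo-minute). If `beta_z` is
#' present the model includes first-order decay of the new transcripts and
#' saturates at `alpha / beta_z`; otherwise accumulation is linear. Values
#' before onset and values below `floor` are clamped to `floor`.
#'
#' @param params named list or vector with `alpha`, `d`, and optionally
#'   `beta_z`.
#' @param t numeric vector of pseudo-minutes.
#' @param floor log2 floor for unexpressed values (default -4).
#' @return log2 expression at each `t`.
#' @examples
#' evaluate_zygotic(list(alpha = 0.01, d = 240), 340)  # log2(0.01 * 100) = 0
#' @export
evaluate_zygotic <- function(params, t, floor = -4) {
  alpha <- params[["alpha"]]; d <- params[["d"]]
  beta_z <- if ("beta_z" %in% names(params)) params[["beta_z"]] else NULL
  dt <- t - d
  y <- rep(floor, length(t))
  pos <- dt > 0
  if (any(pos)) {
    if (is.null(beta_z) || is.na(beta_z)) {
      y[pos] <- log2(alpha) + log2(dt[pos])
    } else {
      y[pos] <- log2(alpha) - log2(beta_z) + log2(1 - exp(-beta_z * dt[pos]))
    }
  }
  pmax(y, floor)
}

## model registry --------------------------------------------------------

MODEL_IDS <- c("M_null", "M_const", "M_decay", "Z_null", "Z_linear", "Z_sat")

model_param_names <- function(model_id) {
  switch(model_id,
    M_null   = character(0),
    M_const  = "x0",
    M_decay  = c("x0", "beta", "d"),
    Z_null   = character(0),
    Z_linear = c("alpha", "d"),
    Z_sat    = c("alpha", "d", "beta_z"),
    stop("unknown model_id: ", model_id, call. = FALSE))
}

model_component <- function(model_id) {
  if (startsWith(model_id, "M_")) "maternal" else "zygotic"
}

#' Default parameter bounds for kinetic model fitting
#'
#' Boxes used both for multistart sampling and as optimizer constraints.
#' They span the plausible range on the normalized-expression scale:
#' half-lives from under 1 to over 7000 pseudo-minutes (`beta` in
#' \code{[1e-4, 1]}), initial levels `x0` in \code{[2^-4, 2^16]},
#' accumulation rates `alpha` in \code{[1e-8, 1]}, and onsets `d` in
#' \code{[0, 360]} so that onsets before the observed window are
#' representable.
#'
#' @param model_id one of `M_null`, `M_const`, `M_decay`, `Z_null`,
#'   `Z_linear`, `Z_sat`.
#' @return named list of `c(lower, upper)` per parameter.
#' @export
default_bounds <- function(model_id) {
  all <- list(
    x0     = c(2^-4, 2^16),
    beta   = c(1e-4, 1),
    d      = c(0, 360),
    alpha  = c(1e-8, 1),
    beta_z = c(1e-4, 1))
  all[model_param_names(model_id)]
}

#' Evaluate any kinetic model curve
#'
#' @param model_id model identifier (see [default_bounds()]).
#' @param params named parameters (ignored for null models).
#' @param t pseudo-minutes.
#' @param floor log2 floor (null models and zygotic curves are clamped here).
#' @return log2 expression at each `t`.
#' @export
model_curve <- function(model_id, params, t, floor = -4) {
  switch(model_id,
    M_null   = rep(floor, length(t)),
    Z_null   = rep(floor, length(t)),
    M_const  = rep(log2(params[["x0"]]), length(t)),
    M_decay  = evaluate_maternal(params, t),
    Z_linear = ,
    Z_sat    = evaluate_zygotic(params, t, floor = floor),
    stop("unknown model_id: ", model_id, call. = FALSE))
}
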