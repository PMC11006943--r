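#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq rnorm rbeta rnbinom rlnorm runif ks.test wilcox.test
#'   p.adjust quantile median sd nlminb setNames rbinom
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## floor a log2 matrix/vector in place, keeping NAs
apply_floor <- function(x, floor) {
  x[!is.na(x) & x < floor] <- floor
  x
}

## derive a child seed from a base seed; stays within 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 12345) %% 2147483647)
}

stopifnot_named <- function(x, what) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named object", call. = FALSE)
}
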