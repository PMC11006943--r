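## Pseudotime rescaling to pseudo-minutes and overlapping bin assignment.

#' Rescale pseudotime from arbitrary units to pseudo-minutes
#'
#' Values below `floor_au` are clamped to `floor_au`, then the clamped range
#' is mapped linearly so its minimum lands on `target[1]` and its maximum on
#' `target[2]` (default 240--360 pseudo-minutes post fertilization).
#'
#' @param pseudotime_au non-negative per-cell pseudotime, arbitrary units.
#' @param floor_au lower clamp in arbitrary units (default 0.1).
#' @param target destination interval, pseudo-minutes.
#' @return per-cell pseudo-minutes.
#' @export
pseudotime_to_minutes <- function(pseudotime_au, floor_au = 0.1,
                                  target = c(240, 360)) {
  stopifnot(all(pseudotime_au >= 0, na.rm = TRUE), target[1] < target[2])
  x <- pmax(pseudotime_au, floor_au)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2])
    stop("pseudotime is constant after clamping; the linear map is degenerate",
         call. = FALSE)
  target[1] + (x - rng[1]) / (rng[2] - rng[1]) * (target[2] - target[1])
}

#' Overlapping pseudotime bin specification
#'
#' Bins start every `step` pseudo-minutes and are `width` wide, so adjacent
#' bins overlap by `width - step`. Intervals are half-open `[start, end)`
#' except the last, which is closed at the range end. With the defaults
#' (10-minute spacing, 13-minute width over 240--360), 12 raw bins arise and
#' the final undersized bin is merged into its predecessor, yielding 11.
#'
#' @param range pseudo-minute range covered.
#' @param step spacing between bin starts.
#' @param width bin width (`width > step` gives overlap).
#' @param merge_undersized_last merge a final bin narrower than `width` into
#'   its predecessor.
#' @return a `bin_spec` with a `bins` matrix (start, end) and interval
#'   midpoints `centers`.
#' @export
bin_spec <- function(range = c(240, 360), step = 10, width = 13,
                     merge_undersized_last = TRUE) {
  stopifnot(range[1] < range[2], step > 0, width >= step)
  n_raw <- ceiling((range[2] - range[1]) / step - 1e-9)
  starts <- range[1] + step * (seq_len(n_raw) - 1)
  ends <- pmin(starts + width, range[2])
  n <- length(starts)
  if (merge_undersized_last && n > 1 && (ends[n] - starts[n]) < width) {
    ends[n - 1] <- ends[n]
    starts <- starts[-n]; ends <- ends[-n]
    n <- n - 1
  }
  bins <- cbind(start = starts, end = ends)
  structure(list(range = range, step = step, width = width,
                 merge_undersized_last = merge_undersized_last,
                 bins = bins, centers = (starts + ends) / 2, n_bins = n),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat("<bin_spec>", x$n_bins, "bins over [", x$range[1], ",", x$range[2],
      "] step", x$step, "width", x$width, "\n")
  invisible(x)
}

#' Assign cells to (possibly overlapping) pseudotime bins
#'
#' Membership is interval containment; a cell in the overlap of two
#' adjacent bins belongs to both. Cells outside the range are clamped to
#' the boundary bin.
#'
#' @param pseudo_min per-cell pseudo-minutes.
#' @param spec a [bin_spec()].
#' @return logical cells x bins membership matrix.
#' @export
assign_bins <- function(pseudo_min, spec = bin_spec()) {
  stopifnot(inherits(spec, "bin_spec"))
  t <- clamp(pseudo_min, spec$range[1], spec$range[2])
  n <- spec$n_bins
  memb <- vapply(seq_len(n), function(b) {
    lo <- spec$bins[b, 1]; hi <- spec$bins[b, 2]
    if (b == n) t >= lo & t <= hi else t >= lo & t < hi
  }, logical(length(t)))
  memb <- matrix(memb, nrow = length(t), ncol = n,
                 dimnames = list(names(pseudo_min),
                                 sprintf("bin_%02d", seq_len(n))))
  memb
}

#' Binned pseudo-bulk expression profiles over pseudotime
#'
#' For each pseudotime bin, all member cells are aggregated to one
#' pseudo-bulk sample and decomposed into total, maternal, and zygotic log2
#' expression (see [pseudobulk_expression()]). Bin centers (interval
#' midpoints by default) serve as the model time axis.
#'
#' @param table a `cell_table` whose `meta` has `pseudotime_au` (or supply
#'   `pseudo_min`).
#' @param spec a [bin_spec()].
#' @param pseudo_min optional precomputed per-cell pseudo-minutes; by
#'   default derived with [pseudotime_to_minutes()].
#' @param scale,floor passed to [pseudobulk_expression()].
#' @param min_cells bins with fewer member cells yield `NA` columns.
#' @return a `binned_profile`: gene x bin matrices `total`, `maternal`,
#'   `zygotic`, bin `centers`, and per-bin `n_cells`.
#' @export
binned_profile <- function(table, spec = bin_spec(), pseudo_min = NULL,
                           scale = 10000, floor = -4, min_cells = 1) {
  stopifnot(inherits(table, "cell_table"))
  if (is.null(pseudo_min))
    pseudo_min <- pseudotime_to_minutes(table$meta$pseudotime_au)
  memb <- assign_bins(pseudo_min, spec)
  ng <- nrow(table$counts)
  genes <- rownames(table$counts)
  empty <- matrix(NA_real_, ng, spec$n_bins,
                  dimnames = list(genes, colnames(memb)))
  out <- list(total = empty, maternal = empty, zygotic = empty)
  n_cells <- integer(spec$n_bins)
  for (b in seq_len(spec$n_bins)) {
    ci <- which(memb[, b])
    n_cells[b] <- length(ci)
    if (length(ci) < min_cells) next
    sub <- subset_cells(table, cells = ci)
    trip <- pseudobulk_expression(sub, grouping = rep("bin", length(ci)),
                                  scale = scale, floor = floor)
    out$total[, b] <- trip$total[, 1]
    if (!is.null(trip$maternal)) {
      out$maternal[, b] <- trip$maternal[, 1]
      out$zygotic[, b] <- trip$zygotic[, 1]
    }
  }
  structure(list(total = out$total, maternal = out$maternal,
                 zygotic = out$zygotic, centers = spec$centers,
                 n_cells = n_cells, spec = spec),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat("<binned_profile>", nrow(x$total), "genes x", length(x$centers),
      "bins; centers", paste(round(x$centers, 1), collapse = " "), "\n")
  invisible(x)
}

#' Write bin definitions and cell memberships as TSV
#'
#' @param spec a [bin_spec()].
#' @param memb logical membership matrix from [assign_bins()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bins <- function(spec, memb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(bin = colnames(memb), start = spec$bins[, 1],
                         end = spec$bins[, 2], center = spec$centers),
              file.path(dir, "bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(memb * 1L, file.path(dir, "cell_bins.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  invisible(dir)
}
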