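#' Define a genomic locus binned at fixed resolution
#'
#' A locus is a half-open genomic interval `[start, end)` partitioned into
#' consecutive bins of `bin_size` bp. All bin indices in this package are
#' 1-based: bin `i` spans `[start + (i-1) * bin_size, start + i * bin_size)`.
#'
#' @param chrom Chromosome name.
#' @param start 0-based start coordinate (bp).
#' @param end End coordinate (bp, exclusive); must exceed `start`.
#' @param bin_size Bin width in bp (default 5000, i.e. 5-KB beads).
#' @return A `locus_spec` object with an `n_bins` field.
#' @examples
#' locus_spec("chrX", 19560000, 20170000)
#' @export
locus_spec <- function(chrom, start, end, bin_size = 5000) {
  stopifnot(is.character(chrom), length(chrom) == 1)
  if (!(end > start)) abort("`end` must be greater than `start`.")
  if (!(bin_size > 0)) abort("`bin_size` must be positive.")
  structure(
    list(
      chrom = chrom, start = as.numeric(start), end = as.numeric(end),
      bin_size = as.numeric(bin_size),
      n_bins = as.integer(ceiling((end - start) / bin_size))
    ),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf(
    "<locus_spec> %s:%s-%s, %d bins of %s bp\n",
    x$chrom, format(x$start, scientific = FALSE),
    format(x$end, scientific = FALSE), x$n_bins,
    format(x$bin_size, scientific = FALSE)
  ))
  invisible(x)
}

#' Map genomic positions to bin indices
#'
#' @param locus A [locus_spec()].
#' @param pos Genomic coordinates (bp, 0-based).
#' @return 1-based bin indices; positions outside the locus give `NA`.
#' @export
bin_of <- function(locus, pos) {
  idx <- floor((pos - locus$start) / locus$bin_size) + 1
  idx[pos < locus$start | pos >= locus$end] <- NA_integer_
  as.integer(idx)
}

#' Bin index to genomic interval
#'
#' @param locus A [locus_spec()].
#' @param bins 1-based bin indices.
#' @return Tibble with `bin`, `start`, `end` (0-based half-open bp).
#' @export
bin_ranges <- function(locus, bins = seq_len(locus$n_bins)) {
  tibble::tibble(
    bin = as.integer(bins),
    start = locus$start + (bins - 1) * locus$bin_size,
    end = pmin(locus$start + bins * locus$bin_size, locus$end)
  )
}

#' Construct a Hi-C contact matrix bound to a locus
#'
#' @param values Symmetric non-negative `n_bins x n_bins` matrix.
#' @param locus A [locus_spec()] whose `n_bins` matches `values`.
#' @param normalized `TRUE` once values are quantile-normalized contact
#'   frequencies on the polymer-ensemble scale, `FALSE` for raw counts.
#' @return A `hic_matrix` object.
#' @export
hic_matrix <- function(values, locus, normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != locus$n_bins || ncol(values) != locus$n_bins) {
    abort(sprintf(
      "Matrix is %d x %d but locus has %d bins.",
      nrow(values), ncol(values), locus$n_bins
    ))
  }
  if (any(!is.finite(values))) abort("Hi-C matrix has non-finite entries.")
  if (any(values < 0)) abort("Hi-C matrix has negative entries.")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    abort("Hi-C matrix is not symmetric (use `symmetrize = TRUE` on load).")
  }
  structure(
    list(values = values, locus = locus, normalized = isTRUE(normalized)),
    class = "hic_matrix"
  )
}

#' @export
print.hic_matrix <- function(x, ...) {
  cat(sprintf(
    "<hic_matrix> %d x %d (%s), %s:%s-%s\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) "normalized frequencies" else "raw",
    x$locus$chrom, format(x$locus$start, scientific = FALSE),
    format(x$locus$end, scientific = FALSE)
  ))
  invisible(x)
}

#' @export
as.matrix.hic_matrix <- function(x, ...) x$values

# Accept either a hic_matrix or a plain matrix; return the matrix.
hic_values <- function(x) {
  if (inherits(x, "hic_matrix")) x$values else as.matrix(x)
}
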