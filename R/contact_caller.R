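#' Quantile-normalize measured Hi-C onto the null-ensemble frequency scale
#'
#' Off-diagonal measured counts are rank-mapped onto the sorted distribution
#' of null-ensemble contact frequencies at the same off-diagonal positions,
#' so simulated frequencies and measured counts become directly comparable.
#' Ties in the measured matrix share averaged target values; rank order is
#' preserved exactly.
#'
#' @param hic A raw [hic_matrix()].
#' @param null_freq The null ensemble's contact-frequency matrix (from
#'   [contact_frequency()]), or a `chromatin_ensemble`.
#' @return A normalized [hic_matrix()] (diagonal set to 1).
#' @export
quantile_normalize_hic <- function(hic, null_freq) {
  if (inherits(null_freq, "chromatin_ensemble")) {
    null_freq <- contact_frequency(null_freq)
  }
  m <- hic_values(hic)
  f <- hic_values(null_freq)
  stopifnot(all(dim(m) == dim(f)))
  ut <- upper.tri(m)
  x <- m[ut]
  if (max(x) == min(x)) {
    abort("Measured matrix is constant off-diagonal; ranks are undefined.")
  }
  target <- sort(f[ut])
  r <- rank(x, ties.method = "average")
  mapped <- approx(seq_along(target), target, xout = r)$y
  out <- m
  out[ut] <- mapped
  out <- t(out)
  out[ut] <- mapped
  diag(out) <- 1
  if (inherits(hic, "hic_matrix")) {
    hic_matrix(out, hic$locus, normalized = TRUE)
  } else {
    out
  }
}

#' Build the per-distance bootstrap null for pairwise contact calling
#'
#' Bag of Little Bootstraps over the null polymer ensemble: each outer
#' replicate draws a subset of `n^subset_exponent` conformations without
#' replacement (probability proportional to importance weight), multinomially
#' resamples it back to full ensemble size, and records, for every
#' genomic-distance stratum `s = |i - j|`, the resampled contact frequency of
#' one pair drawn uniformly at that distance — so the null collection at each
#' distance reflects both the bootstrap resampling noise and the pair-to-pair
#' variation (chain-end effects) of random-fold contact frequencies. The
#' paper-scale setting is 10,000 outer replicates; 1000 is the desk default.
#'
#' @param null_ensemble A `chromatin_ensemble` from [sample_null_ensemble()].
#' @param n_outer Number of outer replicates.
#' @param subset_exponent BLB subset-size exponent (default 0.7).
#' @param seed RNG seed.
#' @return A `contact_null`: replicate-by-stratum frequency matrix plus the
#'   ensemble's point-estimate frequency matrix.
#' @export
build_contact_null <- function(null_ensemble, n_outer = 1000,
                               subset_exponent = 0.7, seed = 1) {
  stopifnot(n_conformations(null_ensemble) >= 1)
  if (n_outer < 100) warn("Fewer than 100 outer replicates: unstable tails.")
  ind <- pair_indicator_cpp(
    null_ensemble$coords, null_ensemble$params$contact_threshold
  )
  n <- nrow(ind)
  n_bins <- dim(null_ensemble$coords)[1]
  w <- ensemble_weights(null_ensemble)
  reps <- blb_distance_reps_cpp(
    ind, w, n_bins, as.integer(n_outer), subset_exponent, as.numeric(seed)
  )
  structure(
    list(
      replicates = reps, ind = ind, weights = w, n_bins = n_bins,
      n_outer = n_outer, subset_exponent = subset_exponent,
      freq_matrix = contact_frequency(null_ensemble),
      n_chains = n, seed = seed
    ),
    class = "contact_null"
  )
}

#' Same-pair bootstrap p-values against a contact null
#'
#' For every bin pair, the add-one proportion of BLB replicates in which the
#' resampled null frequency of that same pair reaches the supplied value:
#' `p = (1 + #\{replicate freq >= value\}) / (1 + n_outer)`. Comparing each
#' pair against its own bootstrap replicate frequencies (rather than pooling
#' pairs across the distance stratum) keeps the test calibrated while
#' retaining power for moderate enrichments; the pooled per-distance
#' collections remain available as `null$replicates`.
#'
#' @param null A `contact_null`.
#' @param values Matrix (or [hic_matrix()]) of frequencies on the ensemble
#'   scale.
#' @param n_outer Number of replicates to evaluate (defaults to the null's
#'   setting; smaller values trade the p-value floor for speed).
#' @return Symmetric matrix of one-sided p-values (NA diagonal).
#' @export
null_pair_pvalues <- function(null, values, n_outer = null$n_outer) {
  m <- hic_values(values)
  n_bins <- null$n_bins
  stopifnot(nrow(m) == n_bins, ncol(m) == n_bins)
  meas <- m[upper.tri(m)] # column-major: matches pair_indicator_cpp order
  exceed <- blb_exceed_cpp(
    null$ind, null$weights, meas, as.integer(n_outer),
    null$subset_exponent, as.numeric(null$seed) + 1
  )
  p <- (1 + exceed) / (1 + n_outer)
  out <- matrix(NA_real_, n_bins, n_bins)
  out[upper.tri(out)] <- p
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' @export
print.contact_null <- function(x, ...) {
  cat(sprintf(
    "<contact_null> %d replicates x %d distance strata (BLB gamma %.2f, %d chains)\n",
    x$n_outer, ncol(x$replicates), x$subset_exponent, x$n_chains
  ))
  invisible(x)
}

#' Call specific pairwise contacts against the bootstrap null
#'
#' For each tested pair `(i, j)` the p-value is the add-one proportion of
#' bootstrap replicate contact frequencies of that pair (at its genomic
#' distance) reaching the normalized measured frequency — see
#' [null_pair_pvalues()]. Benjamini-Hochberg FDR is applied across all tested
#' pairs, and a contact is *specific* when `q < alpha`. The first
#' `exclude_diagonals` diagonals (within 10 KB at 5-KB bins for the default
#' 2) are excluded from testing.
#'
#' @param hic_norm Quantile-normalized [hic_matrix()] (or matrix).
#' @param null A `contact_null` from [build_contact_null()].
#' @param alpha FDR threshold (default 0.05).
#' @param exclude_diagonals Number of near-diagonal strata to skip (default 2).
#' @return A `contact_calls` tibble: `i`, `j`, `distance`,
#'   `normalized_frequency`, `p_value`, `q_value`, `specific`.
#' @export
call_specific_contacts <- function(hic_norm, null, alpha = 0.05,
                                   exclude_diagonals = 2) {
  if (inherits(hic_norm, "hic_matrix") && !hic_norm$normalized) {
    warn("Input Hi-C is not flagged as normalized.")
  }
  m <- hic_values(hic_norm)
  n_bins <- nrow(m)
  if (ncol(null$replicates) != n_bins - 1) {
    abort("Null distribution strata do not match the matrix dimension.")
  }
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  d <- pairs[, 2] - pairs[, 1]
  keep <- d > exclude_diagonals
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  x <- m[pairs]
  pmat <- null_pair_pvalues(null, m)
  p <- pmat[pairs]
  q <- p.adjust(p, method = "BH")
  out <- tibble::tibble(
    i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
    distance = as.integer(d), normalized_frequency = x,
    p_value = p, q_value = q, specific = q < alpha
  )
  structure(out,
    alpha = alpha, exclude_diagonals = exclude_diagonals,
    class = c("contact_calls", class(out))
  )
}

#' Coarse-grain the specific contact set to a minimal driver set
#'
#' Specific pairs are clustered by proximity in the 2-D bin-index plane
#' (hierarchical clustering, average linkage, Chebyshev metric), the tree is
#' cut to `round(retention_fraction * N)` clusters (at least 1), and one
#' representative is retained per cluster: smallest p-value, ties broken by
#' larger normalized frequency then lexicographic pair order. Retaining
#' roughly 5% of specific contacts regularizes the downstream deconvolution.
#'
#' @param calls A `contact_calls` tibble (only `specific` rows are used), or
#'   any tibble with `i`, `j`, `p_value`, `normalized_frequency`.
#' @param retention_fraction Fraction of specific calls to retain (default
#'   0.05).
#' @param linkage Hierarchical linkage (default `"average"`).
#' @return A `coarse_contacts` tibble of all specific calls with `cluster`
#'   and `retained` columns; `attr(, "retained")` holds the representative
#'   subset.
#' @export
coarse_grain_contacts <- function(calls, retention_fraction = 0.05,
                                  linkage = "average") {
  stopifnot(retention_fraction > 0, retention_fraction <= 1)
  spec <- if ("specific" %in% names(calls)) {
    dplyr::filter(calls, .data$specific)
  } else {
    calls
  }
  spec <- tibble::as_tibble(as.data.frame(spec))
  n <- nrow(spec)
  if (n < 1) abort("No specific calls to coarse-grain.")
  k <- max(1L, round(retention_fraction * n))
  if (n == 1) {
    cl <- 1L
  } else {
    hc <- hclust(dist(cbind(spec$i, spec$j), method = "maximum"),
      method = linkage
    )
    cl <- cutree(hc, k = k)
  }
  spec$cluster <- as.integer(cl)
  spec <- dplyr::arrange(
    spec, .data$cluster, .data$p_value,
    dplyr::desc(.data$normalized_frequency), .data$i, .data$j
  )
  spec <- dplyr::mutate(
    dplyr::group_by(spec, .data$cluster),
    retained = dplyr::row_number() == 1
  )
  spec <- dplyr::ungroup(spec)
  spec <- dplyr::arrange(spec, .data$i, .data$j)
  structure(spec,
    retention_fraction = retention_fraction,
    retained = dplyr::filter(spec, .data$retained),
    class = c("coarse_contacts", class(spec))
  )
}

#' Retained representative contacts of a coarse-grained set
#' @param coarse A `coarse_contacts` tibble.
#' @return Tibble of retained representatives.
#' @export
retained_contacts <- function(coarse) {
  dplyr::filter(tibble::as_tibble(as.data.frame(coarse)), .data$retained)
}
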