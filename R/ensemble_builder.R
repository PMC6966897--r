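#' Refold deconvolved cell states into a 3-D ensemble
#'
#' Each cell's active contacts define a constrained sampling problem; the
#' cell is folded into `folds_per_cell` conformations that all satisfy its
#' state at the contact threshold. Cells whose state repeatedly fails to fold
#' (3 retries with fresh seeds) are dropped with a warning. Paper scale is
#' ~50 folds per cell over ~500 cells (an ensemble of 25,000 polymers).
#'
#' @param states `n_cells x M` binary matrix (from [gibbs_deconvolve()]).
#' @param pairs Tibble of the M coarse-grained contacts (`i`, `j`).
#' @param params [polymer_params()].
#' @param n_bins Number of beads.
#' @param folds_per_cell Conformations per cell (default 50).
#' @param seed RNG seed.
#' @return A `reconstructed_ensemble`: combined coordinates, per-conformation
#'   weights, `cell_id` index, the states and pairs, and a dropped-cell count.
#' @export
reconstruct_ensemble <- function(states, pairs, params, n_bins,
                                 folds_per_cell = 50, seed = 1) {
  if (inherits(states, "deconv_fit")) states <- states$states
  pairs <- tibble::as_tibble(as.data.frame(pairs))
  n_cells <- nrow(states)
  coords <- vector("list", n_cells)
  lws <- vector("list", n_cells)
  cell_id <- vector("list", n_cells)
  dropped <- integer(0)
  for (c in seq_len(n_cells)) {
    active <- which(states[c, ] == 1)
    cons <- if (length(active)) {
      cbind(pairs$i[active], pairs$j[active])
    } else {
      NULL
    }
    ens <- NULL
    for (retry in 0:3) {
      ens <- tryCatch(
        sample_constrained_ensemble(
          params, n_bins, cons, folds_per_cell,
          seed = seed + 7919 * c + 104729 * retry
        ),
        chromfold_infeasible_state = function(e) NULL
      )
      if (!is.null(ens)) break
    }
    if (is.null(ens)) {
      dropped <- c(dropped, c)
      next
    }
    coords[[c]] <- ens$coords
    lws[[c]] <- ens$log_weights
    cell_id[[c]] <- rep(c, folds_per_cell)
  }
  if (length(dropped) > 0) {
    warn(sprintf(
      "Dropped %d cell(s) with persistently infeasible states: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  keep <- setdiff(seq_len(n_cells), dropped)
  if (length(keep) == 0) abort("Every cell failed to fold.")
  arr <- array(0, dim = c(n_bins, 3, length(keep) * folds_per_cell))
  w <- numeric(length(keep) * folds_per_cell)
  pos <- 0
  for (c in keep) {
    idx <- pos + seq_len(folds_per_cell)
    arr[, , idx] <- coords[[c]]
    lw <- lws[[c]]
    wc <- exp(lw - max(lw))
    w[idx] <- wc / sum(wc) # each cell contributes equal total mass
    pos <- pos + folds_per_cell
  }
  structure(
    list(
      coords = arr, weights = w / sum(w),
      log_weights = log(w / sum(w)),
      cell_id = unlist(cell_id[keep]), states = states, pairs = pairs,
      params = params, folds_per_cell = folds_per_cell,
      dropped_cells = dropped, seed = seed
    ),
    class = c("reconstructed_ensemble", "chromatin_ensemble")
  )
}

#' @export
print.reconstructed_ensemble <- function(x, ...) {
  cat(sprintf(
    "<reconstructed_ensemble> %d cells x %d folds = %d conformations (%d dropped cells)\n",
    length(unique(x$cell_id)), x$folds_per_cell, n_conformations(x),
    length(x$dropped_cells)
  ))
  invisible(x)
}

#' Simulated Hi-C from a reconstructed ensemble
#'
#' Weighted contact-frequency aggregation over every fold of every cell.
#'
#' @param ensemble A `reconstructed_ensemble` (or any `chromatin_ensemble`).
#' @param locus Optional [locus_spec()] to attach.
#' @return A normalized [hic_matrix()] when `locus` is given, else a matrix.
#' @export
simulated_hic <- function(ensemble, locus = NULL) {
  m <- contact_frequency(ensemble)
  if (is.null(locus)) return(m)
  hic_matrix(m, locus, normalized = TRUE)
}

#' Pearson correlation between Hi-C matrices with diagonal exclusion
#'
#' Correlates upper-triangle entries with `|i - j| > exclude_diagonals`;
#' excluding the first two diagonals removes all frequencies within 10 KB at
#' 5-KB resolution, the convention used for simulated-vs-measured
#' comparisons.
#'
#' @param sim,measured Matrices or [hic_matrix()] of equal dimension.
#' @param exclude_diagonals Diagonals to drop (default 2).
#' @return Pearson correlation.
#' @export
hic_pearson <- function(sim, measured, exclude_diagonals = 2) {
  a <- hic_values(sim)
  b <- hic_values(measured)
  stopifnot(all(dim(a) == dim(b)))
  idx <- which(upper.tri(a), arr.ind = TRUE)
  keep <- idx[, 2] - idx[, 1] > exclude_diagonals
  x <- a[idx[keep, , drop = FALSE]]
  y <- b[idx[keep, , drop = FALSE]]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant matrix: Pearson correlation undefined.")
  }
  cor(x, y)
}

#' Distance-corrected Pearson correlation
#'
#' Computes the Pearson correlation separately within each genomic-distance
#' stratum and combines the per-stratum values as a weighted mean with
#' weights equal to the stratum pair counts, removing the shared distance
#' decay that inflates the plain correlation. Strata with fewer than 3 pairs
#' or zero variance are skipped.
#'
#' @inheritParams hic_pearson
#' @return Weighted mean of per-stratum Pearson correlations.
#' @export
distance_corrected_pearson <- function(sim, measured) {
  a <- hic_values(sim)
  b <- hic_values(measured)
  stopifnot(all(dim(a) == dim(b)))
  n <- nrow(a)
  vals <- numeric(0)
  wts <- numeric(0)
  for (s in seq_len(n - 1)) {
    i <- seq_len(n - s)
    x <- a[cbind(i, i + s)]
    y <- b[cbind(i, i + s)]
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) next
    vals <- c(vals, cor(x, y))
    wts <- c(wts, length(x))
  }
  if (length(vals) == 0) abort("All distance strata are degenerate.")
  sum(vals * wts) / sum(wts)
}

#' Mean pairwise distance matrix of an ensemble
#'
#' @param ensemble A `chromatin_ensemble` or `reconstructed_ensemble`.
#' @param unit `"nm"` (internal) or `"angstrom"` (presentation).
#' @return `n x n` matrix of weighted mean Euclidean distances.
#' @export
mean_distance_matrix <- function(ensemble, unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  w <- if (!is.null(ensemble$weights)) {
    ensemble$weights
  } else {
    ensemble_weights(ensemble)
  }
  d <- mean_distance_cpp(ensemble$coords, w)
  if (unit == "angstrom") d * 10 else d
}

#' Per-cell mean distance matrix
#'
#' @param ensemble A `reconstructed_ensemble`.
#' @param cell_id Cell index.
#' @inheritParams mean_distance_matrix
#' @export
cell_distance_matrix <- function(ensemble, cell_id,
                                 unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  sel <- which(ensemble$cell_id == cell_id)
  if (length(sel) == 0) abort(sprintf("Unknown cell id: %s", cell_id))
  d <- mean_distance_cpp(
    ensemble$coords[, , sel, drop = FALSE], rep(1, length(sel))
  )
  if (unit == "angstrom") d * 10 else d
}

#' Domain boundary-strength profile from a distance matrix
#'
#' Strength at bin `i` is the mean distance between the two flanking
#' `window`-bin blocks (bins `i-window .. i-1` against `i .. i+window-1`)
#' divided by the mean within-block distance of those flanks. Values above 1
#' mark insulation between the flanks, i.e. a domain boundary at `i`. Bins
#' within `window` of the locus ends are undefined (`NA`).
#'
#' @param distance_matrix `n x n` mean pairwise distance matrix.
#' @param window Flank width in bins (default 10, i.e. 50 KB).
#' @return A `boundary_profile` tibble (`bin`, `strength`).
#' @export
boundary_strength <- function(distance_matrix, window = 10) {
  d <- as.matrix(distance_matrix)
  n <- nrow(d)
  if (window < 2) abort("`window` must be at least 2 bins.")
  if (window > floor(n / 2)) abort("`window` exceeds the locus half-length.")
  strength <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - window < 1 || i + window - 1 > n) next
    left <- (i - window):(i - 1)
    right <- i:(i + window - 1)
    cross <- mean(d[left, right])
    wl <- d[left, left][upper.tri(diag(window))]
    wr <- d[right, right][upper.tri(diag(window))]
    within <- mean(c(wl, wr))
    strength[i] <- cross / within
  }
  out <- tibble::tibble(bin = seq_len(n), strength = strength)
  structure(out, window = window, class = c("boundary_profile", class(out)))
}

#' Overlap coefficient between two contact sets
#'
#' `|A intersect B| / min(|A|, |B|)` over bin pairs; used to match external
#' single-cell contact lists to their closest reconstructed cell.
#'
#' @param state_contacts,external_contacts 2-column matrices/data frames of
#'   bin pairs.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_coefficient <- function(state_contacts, external_contacts) {
  a <- as_pair_matrix(state_contacts)
  b <- as_pair_matrix(external_contacts)
  ka <- unique(paste(a[, 1], a[, 2], sep = "_"))
  kb <- unique(paste(b[, 1], b[, 2], sep = "_"))
  if (min(length(ka), length(kb)) == 0) {
    abort("Overlap coefficient undefined for an empty set.")
  }
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}
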