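#' Generate a complete synthetic test world with known ground truth
#'
#' Builds a toy locus with `M` planted contacts arranged as parent/child
#' couples sharing a left anchor (so each couple implies a 3-body triple),
#' a planted dependency DAG (parent contact upregulates its nested child),
#' ground-truth single-cell states sampled from the DAG's conditional
#' Bernoulli model, a folded truth ensemble, the resulting "measured" Hi-C
#' counts (Poisson sampling of the truth contact frequencies), SE/E/P
#' annotations over the planted anchors, SPRITE-like co-capture clusters
#' sliced from the truth conformations, and per-bin feature tracks in which
#' anchor bins carry +1.5 z-units on 3 of 8 tracks.
#'
#' Defaults are the desk-scale world: 100 bins (500 KB at 5-KB beads),
#' M = 12 contacts, 200 cells, 10 folds per cell. Parent contacts activate
#' with probability 0.6; a child activates with probability 0.85 when its
#' parent is active and 0.15 otherwise.
#'
#' @param n_bins Bins in the locus (default 100).
#' @param M Number of planted contacts (default 12; rounded down to an even
#'   count of parent/child couples).
#' @param n_cells Ground-truth cells (default 200).
#' @param folds_per_cell Conformations folded per cell (default 10).
#' @param params [polymer_params()].
#' @param seed RNG seed.
#' @param depth Mean sequencing depth per fully-contacting pair for the
#'   Poisson "measured" counts (default 1000).
#' @param n_clusters Number of SPRITE-like clusters (default 300).
#' @param capture_radius Cluster co-capture radius in nm (default 150).
#' @param activation Named list of planted activation probabilities:
#'   `parent`, `child_on` (child given active parent), `child_off`.
#' @return A `fixture_truth` list; see Details.
#' @export
make_fixture <- function(n_bins = 100, M = 12, n_cells = 200,
                         folds_per_cell = 10, params = polymer_params(),
                         seed = 7, depth = 1000, n_clusters = 300,
                         capture_radius = 150,
                         activation = list(
                           parent = 0.6, child_on = 0.85, child_off = 0.15
                         )) {
  withr::local_seed(seed)
  n_couples <- M %/% 2L
  M <- 2L * n_couples
  locus <- locus_spec("chrS", 0, n_bins * params$bead_bp, params$bead_bp)

  # parent/child couples share a left anchor: parent (a, a+s1) spans further
  # than its nested child (a, a+s2); the triple (a, a+s2, a+s1) is planted.
  rows <- list()
  if (n_couples > 0) {
    hub_gap <- n_bins / n_couples
    for (cpl in seq_len(n_couples)) {
      a <- min(round((cpl - 1) * hub_gap) + sample(2:4, 1), n_bins - 10)
      s1 <- max(8, min(sample(20:28, 1), n_bins - a - 1))
      s2 <- sample(4:max(4, min(13, s1 - 2)), 1)
      rows[[cpl]] <- tibble::tibble(
        contact = c(2L * cpl - 1L, 2L * cpl),
        i = c(a, a), j = c(a + s1, a + s2),
        role = c("parent", "child"), couple = cpl
      )
    }
  }
  pairs <- dplyr::bind_rows(rows)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(
      contact = integer(), i = numeric(), j = numeric(),
      role = character(), couple = integer()
    )
  }
  pairs <- dplyr::arrange(pairs, .data$contact)
  dag_truth <- tibble::tibble(
    from = seq_len(M)[seq_len(M) %% 2L == 1L],
    to = seq_len(M)[seq_len(M) %% 2L == 0L]
  )

  p_parent <- activation$parent
  p_child_on <- activation$child_on
  p_child_off <- activation$child_off
  states <- matrix(0L, n_cells, M)
  for (cpl in seq_len(n_couples)) {
    par <- 2L * cpl - 1L
    chd <- 2L * cpl
    states[, par] <- rbinom(n_cells, 1, p_parent)
    states[, chd] <- rbinom(
      n_cells, 1, ifelse(states[, par] == 1, p_child_on, p_child_off)
    )
  }

  fold_seed <- sample.int(2^30, 1)
  ensemble <- reconstruct_ensemble(
    states, pairs, params, n_bins, folds_per_cell, fold_seed
  )
  target_hic <- hic_matrix(contact_frequency(ensemble), locus,
    normalized = TRUE
  )

  freq <- target_hic$values
  counts <- matrix(0, n_bins, n_bins)
  ut <- upper.tri(counts)
  counts[ut] <- rpois(sum(ut), depth * freq[ut])
  counts <- counts + t(counts)
  diag(counts) <- depth
  measured_hic <- hic_matrix(counts, locus, normalized = FALSE)

  anchor_bins <- sort(unique(c(pairs$i, pairs$j)))
  n_a <- length(anchor_bins)
  lab <- rep(c("SE", "P", "E"), length.out = n_a)
  rng <- bin_ranges(locus, anchor_bins)
  annotations <- tibble::tibble(start = rng$start, end = rng$end, label = lab)
  annotations <- structure(annotations,
    locus = locus,
    class = c("annotation_track", class(annotations))
  )

  clusters <- vector("list", n_clusters)
  n_conf <- n_conformations(ensemble)
  for (k in seq_len(n_clusters)) {
    conf <- ensemble$coords[, , sample.int(n_conf, 1)]
    seed_bead <- sample.int(n_bins, 1)
    d <- sqrt(colSums((t(conf) - conf[seed_bead, ])^2))
    members <- which(d <= capture_radius)
    keep <- members[runif(length(members)) < 0.7]
    clusters[[k]] <- sort(unique(c(seed_bead, keep)))
  }

  track_names <- c(
    "dnase", "polr2a", "nuclear_rna", "h3k4me1", "h3k27ac", "h3k27me3",
    "ctcf", "h3k9me3"
  )
  boosted <- c("dnase", "polr2a", "nuclear_rna")
  features <- tibble::tibble(bin = seq_len(n_bins))
  for (tr in track_names) {
    v <- rnorm(n_bins)
    if (tr %in% boosted) v[anchor_bins] <- v[anchor_bins] + 1.5
    features[[tr]] <- v
  }

  triples <- dplyr::transmute(
    dplyr::filter(pairs, .data$role == "parent"),
    b1 = .data$i,
    b2 = pairs$j[.data$contact + 1L],
    b3 = .data$j
  )

  structure(
    list(
      locus = locus, params = params, pairs = pairs, dag = dag_truth,
      activation = list(
        parent = p_parent, child_on = p_child_on, child_off = p_child_off
      ),
      states = states, ensemble = ensemble, target_hic = target_hic,
      measured_hic = measured_hic, annotations = annotations,
      clusters = clusters, features = features, anchor_bins = anchor_bins,
      planted_triples = triples, depth = depth, seed = seed,
      folds_per_cell = folds_per_cell
    ),
    class = "fixture_truth"
  )
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat(sprintf(
    "<fixture_truth> %d bins, %d planted contacts, %d cells x %d folds\n",
    x$locus$n_bins, nrow(x$pairs), nrow(x$states), x$folds_per_cell
  ))
  invisible(x)
}

#' Generate a synthetic table of specific contact calls
#'
#' Draws `n` distinct bin pairs (outside the excluded near-diagonal band) on
#' an `n_bins` locus and equips them with plausible p/q-values and
#' normalized frequencies, all flagged specific — a lightweight stand-in for
#' a caller output when only the downstream coarse-graining or landscape
#' machinery is exercised.
#'
#' @param n Number of calls (default 300).
#' @param n_bins Locus size in bins (default 100).
#' @param seed RNG seed.
#' @return A `contact_calls` tibble with `specific = TRUE` throughout.
#' @export
synthetic_contact_calls <- function(n = 300, n_bins = 100, seed = 1) {
  withr::local_seed(seed)
  all_pairs <- which(upper.tri(diag(n_bins)), arr.ind = TRUE)
  all_pairs <- all_pairs[all_pairs[, 2] - all_pairs[, 1] > 2, , drop = FALSE]
  stopifnot(nrow(all_pairs) >= n)
  sel <- all_pairs[sample.int(nrow(all_pairs), n), , drop = FALSE]
  p <- sort(runif(n, 1e-5, 1e-3))
  out <- tibble::tibble(
    i = as.integer(sel[, 1]), j = as.integer(sel[, 2]),
    distance = as.integer(sel[, 2] - sel[, 1]),
    normalized_frequency = runif(n, 0.2, 0.9),
    p_value = p, q_value = pmin(1, p * n / rank(p)), specific = TRUE
  )
  structure(out,
    alpha = 0.05, exclude_diagonals = 2,
    class = c("contact_calls", class(out))
  )
}

match_pairs <- function(i, j, ref_i, ref_j, tol = 2) {
  vapply(seq_along(i), function(k) {
    d <- pmax(abs(ref_i - i[k]), abs(ref_j - j[k]))
    if (any(d <= tol)) which.min(d) else NA_integer_
  }, integer(1))
}

#' Score pipeline outputs against fixture ground truth
#'
#' Reports, for whichever outputs are supplied: specific-contact recall
#' (exact planted pairs called specific) and precision (specific calls
#' within 2 bins, Chebyshev, of a planted pair); mean absolute error of
#' deconvolved per-contact marginals against the realized true-state
#' marginals (contacts matched to planted pairs within 2 bins); dependency
#' recall (planted parent/child couples connected by an edge in either
#' direction — orientation is a modeling convention); specific many-body
#' recall of the planted triples; and the Pearson correlation (2-diagonal
#' exclusion) of simulated versus target Hi-C.
#'
#' @param truth A `fixture_truth`.
#' @param calls Optional `contact_calls`.
#' @param marginals Optional tibble `i`, `j`, `marginal` (deconvolved).
#' @param dag Optional `contact_dag`.
#' @param dag_pairs Pairs tibble the DAG nodes refer to (defaults to
#'   `dag$nodes`).
#' @param manybody Optional `manybody_calls` in 3-body mode.
#' @param sim_hic Optional simulated Hi-C matrix.
#' @return Tibble `stage`, `metric`, `value`.
#' @export
score_recovery <- function(truth, calls = NULL, marginals = NULL, dag = NULL,
                           dag_pairs = NULL, manybody = NULL,
                           sim_hic = NULL) {
  out <- list()
  pi <- truth$pairs$i
  pj <- truth$pairs$j
  if (!is.null(calls)) {
    spec <- dplyr::filter(tibble::as_tibble(as.data.frame(calls)),
      .data$specific)
    hit <- vapply(seq_along(pi), function(k) {
      any(spec$i == pi[k] & spec$j == pj[k])
    }, logical(1))
    near <- match_pairs(spec$i, spec$j, pi, pj, tol = 2)
    out$calls <- tibble::tibble(
      stage = "contact_calling",
      metric = c("recall", "precision"),
      value = c(mean(hit), mean(!is.na(near)))
    )
  }
  if (!is.null(marginals)) {
    truth_marg <- colMeans(truth$states)
    m <- match_pairs(marginals$i, marginals$j, pi, pj, tol = 2)
    ok <- !is.na(m)
    err <- abs(marginals$marginal[ok] - truth_marg[m[ok]])
    out$marg <- tibble::tibble(
      stage = "deconvolution",
      metric = c("n_matched", "mean_abs_error", "max_abs_error"),
      value = c(sum(ok), mean(err), max(err))
    )
  }
  if (!is.null(dag)) {
    dag_pairs <- dag_pairs %||% dag$nodes
    node_match <- match_pairs(dag_pairs$i, dag_pairs$j, pi, pj, tol = 2)
    recovered <- vapply(seq_len(nrow(truth$dag)), function(r) {
      a <- which(node_match == truth$dag$from[r])
      b <- which(node_match == truth$dag$to[r])
      if (length(a) == 0 || length(b) == 0) return(FALSE)
      any(dag$edges$from %in% a & dag$edges$to %in% b) ||
        any(dag$edges$from %in% b & dag$edges$to %in% a)
    }, logical(1))
    out$dag <- tibble::tibble(
      stage = "dependency", metric = "edge_recall",
      value = mean(recovered)
    )
  }
  if (!is.null(manybody)) {
    mb <- dplyr::filter(tibble::as_tibble(as.data.frame(manybody)),
      .data$specific)
    tri <- truth$planted_triples
    found <- vapply(seq_len(nrow(tri)), function(r) {
      sig <- paste(sort(c(tri$b1[r], tri$b2[r], tri$b3[r])), collapse = "_")
      sig %in% mb$signature
    }, logical(1))
    out$mb <- tibble::tibble(
      stage = "manybody", metric = "triple_recall", value = mean(found)
    )
  }
  if (!is.null(sim_hic)) {
    out$hic <- tibble::tibble(
      stage = "reconstruction", metric = "pearson_excl2",
      value = hic_pearson(sim_hic, truth$target_hic, exclude_diagonals = 2)
    )
  }
  dplyr::bind_rows(out)
}
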