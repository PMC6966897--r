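#' In-silico knock-in perturbation of one contact
#'
#' Samples a polymer ensemble constrained to contain the knocked-in pair and
#' compares per-pair contact frequencies to the unconstrained baseline: a
#' contact whose frequency rises significantly beyond the random null when
#' another contact is forced is a candidate dependent of that contact. The
#' one-sided p-value compares the perturbed frequency to the stratified
#' bootstrap null at the same genomic distance.
#'
#' @param params [polymer_params()].
#' @param n_bins Number of beads in the locus.
#' @param contact Length-2 vector (or 1-row pair) naming the knocked-in bins.
#' @param null A `contact_null` from [build_contact_null()]; supplies both
#'   the baseline frequencies and the bootstrap replicates.
#' @param n_chains Conformations in the perturbed ensemble (desk default
#'   2000).
#' @param seed RNG seed.
#' @param n_outer Bootstrap replicates evaluated for the per-pair p-values
#'   (default 1000; capped at the null's replicate count).
#' @return A `knockin_result`: matrices `baseline_freq`, `perturbed_freq`,
#'   `delta`, `p_values`, plus the knocked-in pair.
#' @export
knockin <- function(params, n_bins, contact, null, n_chains = 2000,
                    seed = 1, n_outer = 1000) {
  pair <- sort(as.integer(unlist(contact)[1:2]))
  ens <- sample_constrained_ensemble(
    params, n_bins, matrix(pair, ncol = 2), n_chains, seed
  )
  perturbed <- contact_frequency(ens)
  baseline <- null$freq_matrix
  pv <- null_pair_pvalues(null, perturbed,
    n_outer = min(n_outer, null$n_outer)
  )
  structure(
    list(
      knocked_in = pair, baseline_freq = baseline,
      perturbed_freq = perturbed, delta = perturbed - baseline,
      p_values = pv, n_chains = n_chains, seed = seed
    ),
    class = "knockin_result"
  )
}

#' Assemble the knock-in dependency DAG
#'
#' A candidate directed edge `j -> k` exists when the frequency of
#' coarse-grained contact `k` under knock-in of contact `j` is significantly
#' above the stratified null (one-sided, Benjamini-Hochberg across all
#' knock-in/target combinations). Cycles among candidate edges are broken by
#' a frequency-ranked topological order: within any strongly connected
#' component, only edges from the contact with the larger normalized Hi-C
#' frequency to the smaller survive (ties broken lexicographically by pair)
#' — a deterministic, data-driven rule that leaves acyclic candidate sets
#' untouched.
#'
#' @param knockin_results Named or ordered list of `knockin_result`, one per
#'   coarse-grained contact (same order as `pairs`).
#' @param pairs Tibble of the coarse-grained contacts (`i`, `j`, and a
#'   `normalized_frequency` column used for the ordering rule).
#' @param alpha FDR threshold for edges (default 0.05).
#' @param forbidden Optional list of forbidden contact subsets (integer node
#'   indices into `pairs`), e.g. from [detect_infeasible()].
#' @return A `contact_dag`: `nodes` tibble, `edges` tibble and `forbidden`
#'   list. Acyclicity is asserted.
#' @export
build_dependency_dag <- function(knockin_results, pairs, alpha = 0.05,
                                 forbidden = list()) {
  pairs <- tibble::as_tibble(as.data.frame(pairs))
  M <- nrow(pairs)
  stopifnot(length(knockin_results) == M)
  rank_order <- order(
    -pairs$normalized_frequency, pairs$i, pairs$j
  )
  rk <- integer(M)
  rk[rank_order] <- seq_len(M)
  nodes <- dplyr::mutate(pairs, node = dplyr::row_number(), rank = rk)

  cand <- list()
  for (j in seq_len(M)) {
    res <- knockin_results[[j]]
    for (k in seq_len(M)) {
      if (k == j) next
      ik <- pairs$i[k]
      jk <- pairs$j[k]
      cand[[length(cand) + 1]] <- tibble::tibble(
        from = j, to = k,
        delta = res$delta[ik, jk],
        p_value = res$p_values[ik, jk]
      )
    }
  }
  edges <- dplyr::bind_rows(cand)
  if (nrow(edges) > 0) {
    edges$q_value <- p.adjust(edges$p_value, method = "BH")
    edges <- dplyr::filter(edges, .data$q_value < alpha)
    if (nrow(edges) > 0) {
      # break cycles only: within each strongly connected component, keep
      # edges consistent with the frequency-ranked order (higher normalized
      # frequency upstream, ties lexicographic); acyclic edges are untouched
      g <- igraph::graph_from_data_frame(
        edges[, c("from", "to")],
        vertices = data.frame(name = seq_len(M))
      )
      comp <- igraph::components(g, mode = "strong")$membership
      intra <- comp[edges$from] == comp[edges$to]
      edges <- edges[!intra | rk[edges$from] < rk[edges$to], , drop = FALSE]
    }
  } else {
    edges <- tibble::tibble(
      from = integer(), to = integer(), delta = numeric(),
      p_value = numeric(), q_value = numeric()
    )
  }
  dag <- structure(
    list(nodes = nodes, edges = edges, forbidden = forbidden, alpha = alpha),
    class = "contact_dag"
  )
  stopifnot(dag_is_acyclic(dag))
  dag
}

#' @export
print.contact_dag <- function(x, ...) {
  cat(sprintf(
    "<contact_dag> %d contacts, %d edges, %d forbidden subset(s)\n",
    nrow(x$nodes), nrow(x$edges), length(x$forbidden)
  ))
  invisible(x)
}

dag_is_acyclic <- function(dag) {
  if (nrow(dag$edges) == 0) return(TRUE)
  g <- igraph::graph_from_data_frame(
    dag$edges[, c("from", "to")],
    vertices = data.frame(name = seq_len(nrow(dag$nodes)))
  )
  igraph::is_dag(g)
}

#' @describeIn build_dependency_dag Parent sets per node (list of integer
#'   vectors) used by the deconvolution prior.
#' @param dag A `contact_dag`.
#' @export
dag_parents <- function(dag) {
  M <- nrow(dag$nodes)
  out <- rep(list(integer(0)), M)
  if (nrow(dag$edges) > 0) {
    for (r in seq_len(nrow(dag$edges))) {
      k <- dag$edges$to[r]
      out[[k]] <- c(out[[k]], dag$edges$from[r])
    }
  }
  out
}

#' Detect geometrically infeasible contact combinations
#'
#' A subset of coarse-grained contacts is *forbidden* when a fast
#' bound-propagation pre-check ([feasibility_precheck()]) proves it
#' unsatisfiable, or when constrained sampling dead-ends at (by default) 100%
#' of its restart budget. Forbidden sets are closed under superset by
#' construction of [is_forbidden()]; supersets are not re-simulated.
#'
#' @param params [polymer_params()].
#' @param n_bins Number of beads.
#' @param contact_subsets List of integer vectors indexing rows of `pairs`
#'   (pairs and triples by default upstream).
#' @param pairs Tibble of coarse-grained contacts (`i`, `j`).
#' @param n_chains Chains attempted per subset (small; default 50).
#' @param seed RNG seed.
#' @param max_restarts Restart budget used for the dead-end test (default 10).
#' @return List of forbidden subsets (integer vectors).
#' @export
detect_infeasible <- function(params, n_bins, contact_subsets, pairs,
                              n_chains = 50, seed = 1, max_restarts = 10) {
  if (length(contact_subsets) == 0) return(list())
  pairs <- tibble::as_tibble(as.data.frame(pairs))
  params$max_restarts <- as.integer(max_restarts)
  forbidden <- list()
  for (s in seq_along(contact_subsets)) {
    sub <- sort(unique(as.integer(contact_subsets[[s]])))
    if (is_forbidden(sub, forbidden)) {
      forbidden[[length(forbidden) + 1]] <- sub
      next
    }
    cons <- cbind(pairs$i[sub], pairs$j[sub])
    bad <- tryCatch(
      {
        sample_constrained_ensemble(
          params, n_bins, cons, n_chains,
          seed = seed + s
        )
        FALSE
      },
      chromfold_infeasible_state = function(e) TRUE
    )
    if (bad) forbidden[[length(forbidden) + 1]] <- sub
  }
  forbidden
}

#' Is a set of active contacts forbidden?
#'
#' Superset closure: a state is forbidden when any stored forbidden subset is
#' fully contained in its active set.
#'
#' @param active Integer vector of active contact indices.
#' @param forbidden List of forbidden subsets.
#' @export
is_forbidden <- function(active, forbidden) {
  any(vapply(forbidden, function(s) all(s %in% active), logical(1)))
}

#' @export
tidy.contact_dag <- function(x, ...) x$edges

#' @export
glance.contact_dag <- function(x, ...) {
  tibble::tibble(
    n_contacts = nrow(x$nodes), n_edges = nrow(x$edges),
    n_forbidden = length(x$forbidden), alpha = x$alpha
  )
}
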