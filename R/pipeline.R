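#' Run the full Hi-C deconvolution pipeline
#'
#' Orchestrates the whole method on one locus: (1) sample a null polymer
#' ensemble and build the per-distance bootstrap null; (2) quantile-normalize
#' the measured Hi-C onto the ensemble frequency scale and call specific
#' contacts at FDR `alpha`; (3) coarse-grain the specific set to
#' `retention_fraction`; (4) run singleton knock-in perturbations over the
#' retained contacts and assemble the dependency DAG (a fast geometric
#' pre-check screens pairwise/triple infeasibility); (5) Gibbs-deconvolve
#' single-cell states; (6) refold every state into `folds_per_cell`
#' conformations and aggregate the simulated Hi-C.
#'
#' The Gibbs target frequency for a retained contact is background-corrected:
#' the population frequency `f` mixes cells where the contact is an active
#' constraint with cells showing it at the random-fold base rate `b`, so the
#' activation target is `(f - b) / (1 - b)` (clamped to `[0, 1]`).
#'
#' @param measured A raw [hic_matrix()].
#' @param params [polymer_params()].
#' @param n_chains Null-ensemble size (desk default 2000).
#' @param n_outer BLB outer replicates (default 10,000, the reference
#'   setting; the p-value floor 1/(1+n_outer) must undercut the BH threshold
#'   for sparse signals).
#' @param alpha FDR threshold for specific contacts.
#' @param retention_fraction Coarse-graining retention (default 0.05).
#' @param knockin_chains Chains per knock-in perturbation (default
#'   `n_chains`).
#' @param n_cells Deconvolved cells (default 200 at desk scale).
#' @param n_sweeps,burn_in Gibbs schedule.
#' @param folds_per_cell Conformations folded per cell (default 10 at desk
#'   scale).
#' @param prior_boost,sparsity_weight Deconvolution prior settings.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A `chromfold_pipeline` list with every intermediate product:
#'   `null_ensemble`, `null`, `hic_norm`, `calls`, `coarse`, `retained`,
#'   `knockins`, `dag`, `model`, `fit`, `reconstructed`, `sim_hic`, and
#'   summary `metrics`.
#' @export
deconvolve_pipeline <- function(measured, params = polymer_params(),
                                n_chains = 2000, n_outer = 10000,
                                alpha = 0.05, retention_fraction = 0.05,
                                knockin_chains = n_chains, n_cells = 200,
                                n_sweeps = 2000, burn_in = 500,
                                folds_per_cell = 10, prior_boost = exp(1),
                                sparsity_weight = 0.1, seed = 1) {
  locus <- measured$locus
  n_bins <- locus$n_bins
  message(sprintf(
    "[chromfold] seed %d, locus %s:%s-%s (%d bins)",
    seed, locus$chrom, format(locus$start, scientific = FALSE),
    format(locus$end, scientific = FALSE), n_bins
  ))
  null_ens <- sample_null_ensemble(params, n_bins, n_chains, seed = seed)
  null <- build_contact_null(null_ens, n_outer = n_outer, seed = seed + 1)
  hic_norm <- quantile_normalize_hic(measured, null$freq_matrix)
  calls <- call_specific_contacts(hic_norm, null, alpha = alpha)
  message(sprintf(
    "[chromfold] %d of %d tested pairs specific at FDR %.2f",
    sum(calls$specific), nrow(calls), alpha
  ))
  coarse <- coarse_grain_contacts(calls, retention_fraction)
  retained <- retained_contacts(coarse)
  message(sprintf("[chromfold] %d coarse-grained contacts", nrow(retained)))

  knockins <- vector("list", nrow(retained))
  for (m in seq_len(nrow(retained))) {
    knockins[[m]] <- knockin(
      params, n_bins, c(retained$i[m], retained$j[m]), null,
      n_chains = knockin_chains, seed = seed + 100 + m
    )
  }
  # fast geometric screen of pairwise/triple combinations; simulation-based
  # detection is available separately via detect_infeasible()
  forbidden <- list()
  if (nrow(retained) >= 2) {
    subsets <- c(
      utils::combn(nrow(retained), 2, simplify = FALSE),
      if (nrow(retained) >= 3) {
        utils::combn(nrow(retained), 3, simplify = FALSE)
      }
    )
    for (s in subsets) {
      pre <- feasibility_precheck(
        params, n_bins, cbind(retained$i[s], retained$j[s])
      )
      if (!pre$feasible && !is_forbidden(s, forbidden)) {
        forbidden[[length(forbidden) + 1]] <- s
      }
    }
  }
  dag <- build_dependency_dag(knockins, retained,
    alpha = alpha,
    forbidden = forbidden
  )
  message(sprintf(
    "[chromfold] dependency DAG: %d edges, %d forbidden subsets",
    nrow(dag$edges), length(dag$forbidden)
  ))

  f_pop <- hic_norm$values[cbind(retained$i, retained$j)]
  b <- null$freq_matrix[cbind(retained$i, retained$j)]
  f_act <- pmin(pmax((f_pop - b) / (1 - b), 0), 1)
  model <- deconvolution_model(
    f_act,
    dag = dag, prior_boost = prior_boost,
    sparsity_weight = sparsity_weight, n_cells = n_cells
  )
  fit <- gibbs_deconvolve(model,
    n_sweeps = n_sweeps, burn_in = burn_in,
    seed = seed + 2
  )
  recon <- reconstruct_ensemble(
    fit$states, retained, params, n_bins, folds_per_cell,
    seed = seed + 3
  )
  sim <- simulated_hic(recon, locus)
  metrics <- tibble::tibble(
    pearson_excl2 = hic_pearson(sim, hic_norm, exclude_diagonals = 2),
    distance_corrected = distance_corrected_pearson(sim, hic_norm),
    n_specific = sum(calls$specific), n_retained = nrow(retained),
    n_dag_edges = nrow(dag$edges), n_cells = n_cells,
    n_conformations = n_conformations(recon)
  )
  message(sprintf(
    "[chromfold] simulated-vs-normalized Hi-C Pearson (excl. 2 diagonals): %.4f",
    metrics$pearson_excl2
  ))
  structure(
    list(
      locus = locus, params = params, null_ensemble = null_ens, null = null,
      hic_norm = hic_norm, calls = calls, coarse = coarse,
      retained = retained, knockins = knockins, dag = dag, model = model,
      fit = fit, reconstructed = recon, sim_hic = sim, metrics = metrics,
      seed = seed
    ),
    class = "chromfold_pipeline"
  )
}

#' @export
print.chromfold_pipeline <- function(x, ...) {
  cat("<chromfold_pipeline>\n")
  print(x$metrics)
  invisible(x)
}
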