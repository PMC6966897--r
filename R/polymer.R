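#' Polymer model parameters
#'
#' Geometry of the coarse-grained chromatin chain: each bead represents
#' `bead_bp` bp of chromatin fiber of diameter `fiber_diameter` nm (excluded
#' volume), consecutive beads sit exactly `bond_length` nm apart, and two bins
#' are "in contact" when their beads are within `contact_threshold` nm
#' (a cross-linking distance). Chains are confined to a sphere whose radius
#' preserves a constant nuclear base-pair density `bp_density` (bp per nm^3);
#' by default that density is derived from a declared nuclear diameter and
#' genome size rather than fitted.
#'
#' @param bead_bp bp per bead (default 5000).
#' @param fiber_diameter Chromatin fiber diameter in nm (default 11); also the
#'   hard-sphere excluded-volume distance between non-bonded beads.
#' @param contact_threshold Contact (cross-linking) distance in nm (default 80).
#' @param bond_length Center-to-center step between consecutive beads in nm
#'   (default 30; a declared constant, must be at least `fiber_diameter`).
#' @param bp_density bp per nm^3 used to scale the confinement sphere. If
#'   `NULL`, computed as `genome_bp` divided by the volume of a sphere of
#'   diameter `nuclear_diameter`.
#' @param nuclear_diameter Nuclear diameter in nm (default 7000, a typical
#'   lymphoblastoid nucleus).
#' @param genome_bp Genome size in bp sharing the nuclear volume (default
#'   6.2e9, diploid human).
#' @param confinement_radius Optional fixed confinement radius (nm); when
#'   `NULL` it is derived per locus from `bp_density`.
#' @param n_candidates Candidate directions evaluated per growth step.
#' @param checkpoint_every Growth checkpoint interval (beads) for
#'   resampling/enrichment.
#' @param max_restarts Maximum growth restarts before failing.
#' @return A `polymer_params` object.
#' @export
polymer_params <- function(bead_bp = 5000, fiber_diameter = 11,
                           contact_threshold = 80, bond_length = 30,
                           bp_density = NULL, nuclear_diameter = 7000,
                           genome_bp = 6.2e9, confinement_radius = NULL,
                           n_candidates = 50, checkpoint_every = 10,
                           max_restarts = 100) {
  if (is.null(bp_density)) {
    bp_density <- genome_bp / ((4 / 3) * pi * (nuclear_diameter / 2)^3)
  }
  p <- list(
    bead_bp = bead_bp, fiber_diameter = fiber_diameter,
    contact_threshold = contact_threshold, bond_length = bond_length,
    bp_density = bp_density, confinement_radius = confinement_radius,
    n_candidates = as.integer(n_candidates),
    checkpoint_every = as.integer(checkpoint_every),
    max_restarts = as.integer(max_restarts)
  )
  stopifnot(
    p$bead_bp > 0, p$fiber_diameter > 0, p$bond_length > 0,
    p$bp_density > 0, p$n_candidates >= 1, p$checkpoint_every >= 1
  )
  if (!(p$contact_threshold > p$fiber_diameter)) {
    abort("`contact_threshold` must exceed `fiber_diameter`.")
  }
  if (p$bond_length < p$fiber_diameter) {
    abort("`bond_length` must be at least `fiber_diameter` (hard spheres).")
  }
  structure(p, class = "polymer_params")
}

#' Confinement radius preserving constant base-pair density
#'
#' The locus of `L` bp is confined to a sphere whose volume satisfies
#' `L / volume == bp_density`, i.e. `radius = (3 L / (4 pi rho))^(1/3)`.
#'
#' @param locus A [locus_spec()], or a bead count when `params$bead_bp` should
#'   supply the bp length.
#' @param params [polymer_params()].
#' @return Radius in nm.
#' @export
confinement_radius_for <- function(locus, params) {
  L <- if (inherits(locus, "locus_spec")) {
    locus$end - locus$start
  } else {
    as.numeric(locus) * params$bead_bp
  }
  (3 * L / (4 * pi * params$bp_density))^(1 / 3)
}

resolve_radius <- function(params, n_bins) {
  params$confinement_radius %||% confinement_radius_for(n_bins, params)
}

as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.data.frame(pairs) && nrow(pairs) == 0)) {
    return(matrix(integer(0), ncol = 2))
  }
  m <- if (is.data.frame(pairs)) {
    cbind(pairs[[1]], pairs[[2]])
  } else if (is.matrix(pairs)) {
    pairs
  } else {
    matrix(as.integer(pairs), ncol = 2, byrow = TRUE)
  }
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  storage.mode(m) <- "integer"
  m
}

# Shared SMC driver. Returns a chromatin_ensemble or signals a classed error.
smc_ensemble <- function(params, n_bins, n_chains, constraints, seed,
                         resample = TRUE, kind = "null") {
  stopifnot(n_chains >= 1, n_bins >= 2)
  radius <- resolve_radius(params, n_bins)
  if (!(radius > params$bond_length)) {
    abort("Confinement radius must exceed the bond length.")
  }
  cons <- as_pair_matrix(constraints)
  if (nrow(cons) > 0) {
    if (any(cons < 1) || any(cons > n_bins) || any(cons[, 1] == cons[, 2])) {
      abort("Constraint pairs must be distinct bins within the locus.")
    }
    pre <- feasibility_precheck(params, n_bins, cons)
    if (!pre$feasible) {
      abort(
        paste0(
          "Contact state is geometrically infeasible: ",
          paste(pre$violations, collapse = "; ")
        ),
        class = "chromfold_infeasible_state"
      )
    }
  }
  res <- smc_sample_cpp(
    n_bins, n_chains, params$bond_length, params$fiber_diameter,
    params$contact_threshold, radius, cons - 1L, params$n_candidates,
    params$checkpoint_every, params$max_restarts, as.numeric(seed), resample
  )
  if (!res$success) {
    msg <- sprintf(
      "Chain growth dead-ended persistently (longest partial: %d of %d beads).",
      res$longest_partial, n_bins
    )
    if (nrow(cons) > 0) {
      abort(
        paste0(
          msg, " Offending constraint pairs: ",
          paste(sprintf("(%d,%d)", cons[, 1], cons[, 2]), collapse = ", ")
        ),
        class = "chromfold_infeasible_state"
      )
    }
    abort(msg, class = "chromfold_folding_failure")
  }
  if (kind == "null" && res$dead_ends > 0.5 * res$chain_starts) {
    abort(
      sprintf(
        "More than 50%% of growth attempts dead-ended (%d of %d); review polymer parameters.",
        as.integer(res$dead_ends), as.integer(res$chain_starts)
      ),
      class = "chromfold_folding_failure"
    )
  }
  structure(
    list(
      coords = res$coords, log_weights = res$log_weights, params = params,
      kind = kind,
      constraint_set = if (nrow(cons) > 0) cons else NULL,
      confinement_radius = radius, seed = seed,
      diagnostics = list(
        dead_ends = res$dead_ends, chain_starts = res$chain_starts,
        restarts = res$restarts
      )
    ),
    class = "chromatin_ensemble"
  )
}

#' Grow a single confined self-avoiding chain
#'
#' Sequential chain growth with Rosenbluth-style importance weighting: at each
#' step `n_candidates` uniform directions are screened against excluded
#' volume, confinement and (optionally) required-contact look-ahead, one
#' survivor is chosen uniformly, and the log-weight accumulates the log
#' survival fraction so that weighted averages target the uniform distribution
#' over feasible chains.
#'
#' @param params [polymer_params()].
#' @param n_bins Number of beads.
#' @param required_contacts Optional bin pairs (2-column matrix/data frame,
#'   1-based) that must end within `contact_threshold`.
#' @param seed RNG seed.
#' @return A `conformation`: list with `coords` (`n_bins x 3` nm matrix),
#'   `log_weight` and `seed`.
#' @export
grow_chain <- function(params, n_bins, required_contacts = NULL, seed = 1) {
  ens <- smc_ensemble(params, n_bins, 1L, required_contacts, seed,
    resample = FALSE,
    kind = if (is.null(required_contacts)) "null" else "constrained"
  )
  structure(
    list(
      coords = ens$coords[, , 1], log_weight = ens$log_weights[1], seed = seed
    ),
    class = "conformation"
  )
}

#' Sample a null (unconstrained) polymer ensemble
#'
#' Grows `n_chains` confined self-avoiding chains in lockstep with
#' weight-based enrichment: at fixed growth checkpoints the population is
#' systematically resampled whenever the effective sample size drops below
#' half the population (or any chain has dead-ended), yielding a near-uniform
#' importance-weighted ensemble of random folds that serves as the null model
#' for contact calling. Paper-scale runs use hundreds of thousands of chains;
#' the desk default in examples and tests is about 2000.
#'
#' @inheritParams grow_chain
#' @param n_chains Number of conformations.
#' @return A `chromatin_ensemble`.
#' @export
sample_null_ensemble <- function(params, n_bins, n_chains, seed = 1) {
  smc_ensemble(params, n_bins, n_chains, NULL, seed, kind = "null")
}

#' Sample an ensemble conditioned on a contact state
#'
#' Every returned conformation satisfies every required pair at Euclidean
#' distance at most `contact_threshold`; weights target uniformity over the
#' constrained set. An empty `contact_state` reduces to
#' [sample_null_ensemble()].
#'
#' @inheritParams sample_null_ensemble
#' @param contact_state Bin pairs (2-column matrix/data frame, 1-based) that
#'   must be in contact.
#' @return A `chromatin_ensemble` of kind `"constrained"`.
#' @export
sample_constrained_ensemble <- function(params, n_bins, contact_state,
                                        n_chains, seed = 1) {
  cons <- as_pair_matrix(contact_state)
  smc_ensemble(params, n_bins, n_chains, cons, seed,
    kind = if (nrow(cons) > 0) "constrained" else "null"
  )
}

#' @export
print.chromatin_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf(
    "<chromatin_ensemble> %d conformations x %d beads (%s), radius %.1f nm\n",
    d[3], d[1], x$kind, x$confinement_radius
  ))
  invisible(x)
}

#' Number of conformations in an ensemble
#' @param ensemble A `chromatin_ensemble` or `reconstructed_ensemble`.
#' @export
n_conformations <- function(ensemble) dim(ensemble$coords)[3]

#' Normalized importance weights of an ensemble
#' @param ensemble A `chromatin_ensemble`.
#' @return Weights summing to 1.
#' @export
ensemble_weights <- function(ensemble) {
  lw <- ensemble$log_weights
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Extract one conformation's coordinates
#' @param ensemble A `chromatin_ensemble`.
#' @param k Conformation index.
#' @return `n_bins x 3` matrix (nm).
#' @export
conformation <- function(ensemble, k) ensemble$coords[, , k]

#' Weighted ensemble contact frequency matrix
#'
#' Entry `(i, j)` is the importance-weighted fraction of conformations in
#' which beads `i` and `j` are within the contact threshold; the diagonal is
#' 1 and the matrix is symmetric.
#'
#' @param ensemble A `chromatin_ensemble` (or reconstructed ensemble).
#' @param threshold Contact distance in nm; defaults to the ensemble's
#'   `contact_threshold`.
#' @return `n_bins x n_bins` numeric matrix.
#' @export
contact_frequency <- function(ensemble, threshold = NULL) {
  stopifnot(n_conformations(ensemble) >= 1)
  thr <- threshold %||% ensemble$params$contact_threshold
  contact_frequency_cpp(ensemble$coords, ensemble_weights(ensemble), thr)
}

#' Geometric feasibility pre-check for a constraint set
#'
#' Propagates distance upper bounds along the chain (exact `bond_length`
#' steps) and through required contacts (`contact_threshold` edges) by
#' shortest paths, and flags the set infeasible when an implied upper bound
#' undercuts a hard lower bound (the bond length for adjacent beads, the
#' fiber diameter otherwise). This catches contour/triangle-inequality
#' violations cheaply; subtler infeasibility is discovered by simulation in
#' [detect_infeasible()].
#'
#' @param params [polymer_params()].
#' @param n_bins Number of beads.
#' @param pairs Constraint pairs (2-column, 1-based).
#' @return List with `feasible` flag and `violations` messages.
#' @export
feasibility_precheck <- function(params, n_bins, pairs) {
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0) return(list(feasible = TRUE, violations = character()))
  g <- igraph::make_empty_graph(n = n_bins, directed = FALSE)
  chain <- cbind(seq_len(n_bins - 1), 2:n_bins)
  g <- igraph::add_edges(g, t(chain), weight = params$bond_length)
  g <- igraph::add_edges(g, t(pairs), weight = params$contact_threshold)
  verts <- sort(unique(c(pairs[, 1], pairs[, 2],
                         pmin(pairs + 1, n_bins), pmax(pairs - 1, 1))))
  d <- igraph::distances(g, v = verts, to = verts)
  viol <- character()
  for (a in seq_along(verts)) {
    for (b in seq_along(verts)) {
      i <- verts[a]; j <- verts[b]
      if (j <= i) next
      lower <- if (j - i == 1) params$bond_length else params$fiber_diameter
      if (d[a, b] < lower - 1e-9) {
        viol <- c(viol, sprintf(
          "beads %d-%d: implied max distance %.1f nm < minimum %.1f nm",
          i, j, d[a, b], lower
        ))
      }
    }
  }
  list(feasible = length(viol) == 0, violations = viol)
}
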