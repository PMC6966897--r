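#' Bayesian deconvolution model over coarse-grained contacts
#'
#' The generative stand-in: each of `n_cells` cells carries a binary state
#' over the M coarse-grained contacts; the per-contact active counts
#' `k_j = sum_c s_cj` are tied to the normalized Hi-C target frequencies
#' `f_j` through a Binomial(`n_cells`, `f_j`) likelihood. The prior on a cell
#' state sums, over active contacts, a base log-odds `logit(f_j)` plus
#' `log(prior_boost)` when at least one DAG parent is active, minus a
#' sparsity penalty per active contact; states activating a forbidden subset
#' have zero prior mass.
#'
#' @param target_freq Per-contact target frequencies `f_j` in `[0, 1]`
#'   (normalized Hi-C at the coarse-grained pairs); clamped to
#'   `[1e-6, 1 - 1e-6]`.
#' @param dag Optional [build_dependency_dag()] result (supplies parents and
#'   forbidden subsets).
#' @param prior_boost Multiplicative odds boost for a parent-supported
#'   contact (default `exp(1)`, one nat).
#' @param sparsity_weight Prior penalty per active contact (default 0.1).
#' @param n_cells Number of deconvolved cells (default 500, i.e. 25,000
#'   polymers at 50 folds per cell).
#' @return A `deconv_model`.
#' @export
deconvolution_model <- function(target_freq, dag = NULL, prior_boost = exp(1),
                                sparsity_weight = 0.1, n_cells = 500) {
  f <- pmin(pmax(as.numeric(target_freq), 1e-6), 1 - 1e-6)
  stopifnot(prior_boost >= 1, n_cells >= 1)
  M <- length(f)
  parents <- if (is.null(dag)) rep(list(integer(0)), M) else dag_parents(dag)
  forbidden <- if (is.null(dag)) list() else dag$forbidden
  stopifnot(length(parents) == M)
  structure(
    list(
      f = f, M = M, parents = parents, forbidden = forbidden,
      log_boost = log(prior_boost), sparsity = sparsity_weight,
      n_cells = as.integer(n_cells)
    ),
    class = "deconv_model"
  )
}

#' @export
print.deconv_model <- function(x, ...) {
  cat(sprintf(
    "<deconv_model> %d contacts x %d cells, boost e^%.2f, sparsity %.2f, %d forbidden\n",
    x$M, x$n_cells, x$log_boost, x$sparsity, length(x$forbidden)
  ))
  invisible(x)
}

#' Unnormalized log-prior of cell states
#'
#' `-Inf` when any forbidden subset is fully active in some cell; otherwise
#' the sum over cells and active contacts of
#' `logit(f_j) + log(prior_boost) * [any parent active] - sparsity_weight`.
#' The all-zero state scores 0 (empty sum).
#'
#' @param states Binary vector (one cell) or `n_cells x M` matrix.
#' @param model A `deconv_model`.
#' @return Scalar log-prior (unnormalized).
#' @export
state_log_prior <- function(states, model) {
  s <- if (is.matrix(states)) states else matrix(states, nrow = 1)
  stopifnot(ncol(s) == model$M)
  lp <- 0
  base <- log(model$f / (1 - model$f))
  for (c in seq_len(nrow(s))) {
    active <- which(s[c, ] == 1)
    if (is_forbidden(active, model$forbidden)) return(-Inf)
    for (j in active) {
      lp <- lp + base[j] - model$sparsity
      if (any(model$parents[[j]] %in% active)) lp <- lp + model$log_boost
    }
  }
  lp
}

#' Binomial log-likelihood of cell states given target frequencies
#'
#' @param states `n_cells x M` binary matrix (all cells).
#' @param model A `deconv_model` with matching `n_cells`.
#' @return `sum_j log Binom(k_j; n_cells, f_j)` with `k_j` the active counts.
#' @export
states_log_likelihood <- function(states, model) {
  s <- if (is.matrix(states)) states else matrix(states, nrow = 1)
  stopifnot(nrow(s) == model$n_cells, ncol(s) == model$M)
  k <- colSums(s)
  sum(dbinom(k, model$n_cells, model$f, log = TRUE))
}

#' Gibbs sampling of single-cell contact states
#'
#' Systematic-scan Gibbs over every (cell, contact) site: the flip
#' probability combines the prior term (base odds, parent boost including
#' boosts a flip grants or removes for the contact's children, sparsity) with
#' the likelihood change in the contact's active count. Forbidden subsets are
#' never completed. Returns the final post-burn-in states, the log-posterior
#' trace and (optionally) thinned state samples.
#'
#' @param model A `deconv_model`.
#' @param n_sweeps Total sweeps (default 2000).
#' @param burn_in Burn-in sweeps (default 500).
#' @param seed RNG seed.
#' @param record_every Record the joint state every this many post-burn-in
#'   sweeps (0 = none).
#' @return A `deconv_fit`: `states` matrix, `trace` tibble, optional
#'   `samples`, and the model.
#' @export
gibbs_deconvolve <- function(model, n_sweeps = 2000, burn_in = 500, seed = 1,
                             record_every = 0) {
  stopifnot(burn_in < n_sweeps)
  withr::local_seed(seed)
  init <- NULL
  for (attempt in seq_len(10)) {
    cand <- matrix(
      rbinom(model$n_cells * model$M, 1, rep(model$f, each = model$n_cells)),
      model$n_cells, model$M
    )
    ok <- TRUE
    for (c in seq_len(model$n_cells)) {
      for (retry in seq_len(10)) {
        if (!is_forbidden(which(cand[c, ] == 1), model$forbidden)) break
        cand[c, ] <- rbinom(model$M, 1, model$f)
      }
      if (is_forbidden(which(cand[c, ] == 1), model$forbidden)) ok <- FALSE
    }
    if (ok && is.finite(state_log_prior(cand, model) +
      states_log_likelihood(cand, model))) {
      init <- cand
      break
    }
  }
  if (is.null(init)) abort("Could not initialize a finite-posterior state.")
  lbinom <- outer(
    0:model$n_cells, seq_len(model$M),
    function(k, j) dbinom(k, model$n_cells, model$f[j], log = TRUE)
  )
  res <- gibbs_cpp(
    init, log(model$f / (1 - model$f)), lbinom,
    lapply(model$parents, as.integer), lapply(model$forbidden, as.integer),
    model$log_boost, model$sparsity, as.integer(n_sweeps),
    as.integer(burn_in), as.integer(record_every),
    as.numeric(sample.int(.Machine$integer.max, 1))
  )
  structure(
    list(
      states = res$states,
      trace = tibble::tibble(
        sweep = seq_len(n_sweeps), log_posterior = as.numeric(res$trace)
      ),
      samples = if (record_every > 0) res$samples else NULL,
      model = model, n_sweeps = n_sweeps, burn_in = burn_in, seed = seed
    ),
    class = "deconv_fit"
  )
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf(
    "<deconv_fit> %d cells x %d contacts, %d sweeps (burn-in %d), final logpost %.2f\n",
    nrow(x$states), ncol(x$states), x$n_sweeps, x$burn_in,
    x$trace$log_posterior[x$n_sweeps]
  ))
  invisible(x)
}

#' @export
tidy.deconv_fit <- function(x, ...) {
  tibble::tibble(
    contact = seq_len(x$model$M),
    target_frequency = x$model$f,
    marginal = colMeans(x$states)
  )
}

#' @export
glance.deconv_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$states), n_contacts = ncol(x$states),
    n_sweeps = x$n_sweeps,
    log_posterior = x$trace$log_posterior[x$n_sweeps],
    vs_naive = compare_to_naive(x)$difference
  )
}

#' Compare the structured model to the naive independent-contact model
#'
#' Evaluates, on the same sampled states, the structured log-posterior
#' (DAG/forbidden prior plus binomial likelihood) minus the log-probability
#' under a naive model of independent Bernoulli(`f_j`) contacts per cell.
#' A positive difference indicates the dependency structure explains the
#' deconvolved states better than independence.
#'
#' @param fit A `deconv_fit`, or a binary states matrix.
#' @param model Required when `fit` is a plain matrix.
#' @return List with `structured`, `naive` and `difference` (all log scale).
#' @export
compare_to_naive <- function(fit, model = NULL) {
  if (inherits(fit, "deconv_fit")) {
    states <- fit$states
    model <- fit$model
  } else {
    states <- fit
    stopifnot(!is.null(model))
  }
  structured <- state_log_prior(states, model) +
    states_log_likelihood(states, model)
  naive <- sum(dbinom(
    states, 1, matrix(model$f, nrow(states), model$M, byrow = TRUE),
    log = TRUE
  ))
  list(structured = structured, naive = naive,
       difference = structured - naive)
}
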