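toy_dag <- function(f = c(0.55, 0.45), forbidden = list()) {
  structure(
    list(
      nodes = tibble::tibble(
        i = c(1L, 1L), j = c(9L, 5L), node = 1:2, rank = 1:2,
        normalized_frequency = f
      ),
      edges = tibble::tibble(
        from = 1L, to = 2L, delta = 0.2, p_value = 1e-4, q_value = 1e-3
      ),
      forbidden = forbidden, alpha = 0.05
    ),
    class = "contact_dag"
  )
}

test_that("the log-prior has its stated closed forms", {
  model <- deconvolution_model(c(0.55, 0.45),
    dag = toy_dag(),
    prior_boost = exp(1), sparsity_weight = 0.1, n_cells = 1
  )
  # all-zero state scores 0 (empty sum)
  expect_equal(state_log_prior(c(0, 0), model), 0)
  # activating a parent-supported contact adds base odds + boost - sparsity
  base2 <- log(model$f[2] / (1 - model$f[2]))
  d <- state_log_prior(c(1, 1), model) - state_log_prior(c(1, 0), model)
  expect_equal(d, base2 + 1 - 0.1, tolerance = 1e-12)
  # without the parent, no boost
  d0 <- state_log_prior(c(0, 1), model) - state_log_prior(c(0, 0), model)
  expect_equal(d0, base2 - 0.1, tolerance = 1e-12)
})

test_that("forbidden subsets zero out the prior", {
  model <- deconvolution_model(c(0.5, 0.5),
    dag = toy_dag(forbidden = list(c(1L, 2L))), n_cells = 1
  )
  expect_identical(state_log_prior(c(1, 1), model), -Inf)
  expect_true(is.finite(state_log_prior(c(1, 0), model)))
})

test_that("the binomial likelihood matches closed forms and is unimodal", {
  model <- deconvolution_model(0.5, n_cells = 2)
  # single contact, f = 0.5, n = 2, k = 1: Binom(1; 2, 0.5) = 0.5
  expect_equal(
    states_log_likelihood(matrix(c(1, 0), 2, 1), model), log(0.5)
  )
  m100 <- deconvolution_model(0.37, n_cells = 100)
  ll_of_k <- function(k) {
    s <- matrix(0, 100, 1)
    if (k > 0) s[seq_len(k), 1] <- 1
    states_log_likelihood(s, m100)
  }
  ks <- 0:100
  lls <- vapply(ks, ll_of_k, numeric(1))
  expect_equal(ks[which.max(lls)], round(100 * 0.37))
  # doubling the deviation from n*f strictly decreases the likelihood
  expect_gt(ll_of_k(37 + 5), ll_of_k(37 + 10))
  expect_gt(ll_of_k(37 - 5), ll_of_k(37 - 10))
})

test_that("single-site Gibbs tracks the binomial target", {
  model <- deconvolution_model(0.6, n_cells = 100, sparsity_weight = 0)
  fit <- gibbs_deconvolve(model, n_sweeps = 500, burn_in = 100, seed = 2)
  k <- sum(fit$states)
  expect_lt(abs(k - 60), 3 * sqrt(100 * 0.6 * 0.4))
})

test_that("forbidden pairs are never jointly active in sampled states", {
  model <- deconvolution_model(c(0.7, 0.7),
    dag = toy_dag(forbidden = list(c(1L, 2L))), n_cells = 50
  )
  fit <- gibbs_deconvolve(model,
    n_sweeps = 400, burn_in = 100, seed = 3,
    record_every = 1
  )
  expect_true(all(rowSums(fit$states) <= 1))
  # and in every recorded sample along the chain
  both <- fit$samples[, seq_len(50)] + fit$samples[, 50 + seq_len(50)]
  expect_true(all(both <= 1))
})

test_that("Gibbs recovers aggregated ground-truth marginals on the fixture", {
  fx <- fx_small()
  f <- colMeans(fx$states)
  model <- deconvolution_model(f, n_cells = nrow(fx$states))
  fit <- gibbs_deconvolve(model, n_sweeps = 1500, burn_in = 400, seed = 1)
  expect_lte(max(abs(colMeans(fit$states) - f)), 0.05 + 1e-9)
})

test_that("compare_to_naive reduces to prior terms for an edgeless flat model", {
  f <- c(0.3, 0.6)
  model <- deconvolution_model(f, n_cells = 2, sparsity_weight = 0)
  states <- matrix(c(1L, 0L, 1L, 1L), 2, 2)
  res <- compare_to_naive(states, model)
  # independent arithmetic: prior = sum over active of logit(f);
  # likelihood = sum_j log Binom(k_j; 2, f_j); naive = Bernoulli product
  k <- colSums(states)
  structured <- sum(states %*% log(f / (1 - f))) +
    sum(dbinom(k, 2, f, log = TRUE))
  naive <- sum(dbinom(states, 1,
    matrix(f, 2, 2, byrow = TRUE),
    log = TRUE
  ))
  expect_equal(res$structured, structured, tolerance = 1e-10)
  expect_equal(res$difference, structured - naive, tolerance = 1e-10)
})

test_that("states from planted dependencies favour the structured model", {
  fx <- fx_small()
  f <- colMeans(fx$states)
  dag <- structure(
    list(
      nodes = dplyr::mutate(fx$pairs,
        node = .data$contact,
        normalized_frequency = f
      ),
      edges = dplyr::mutate(fx$dag, delta = 0.2, p_value = 1e-4, q_value = 1e-3),
      forbidden = list(), alpha = 0.05
    ),
    class = "contact_dag"
  )
  model <- deconvolution_model(f,
    dag = dag, prior_boost = exp(1),
    sparsity_weight = 0, n_cells = nrow(fx$states)
  )
  expect_gt(compare_to_naive(fx$states, model)$difference, 0)
})

test_that("naive samples never beat the naive model in expectation", {
  # Gibbs-inequality check on an enumerable toy: E_q[log p_norm - log q] <= 0
  f <- c(0.55, 0.45)
  model <- deconvolution_model(f, dag = toy_dag(f), n_cells = 2)
  states_of <- function(id) matrix(as.integer(intToBits(id))[1:4], 2, 2)
  lp <- vapply(0:15, function(id) {
    s <- states_of(id)
    state_log_prior(s, model) + states_log_likelihood(s, model)
  }, numeric(1))
  logZ <- max(lp) + log(sum(exp(lp - max(lp))))
  set.seed(4)
  diffs <- replicate(2000, {
    s <- matrix(rbinom(4, 1, rep(model$f, each = 2)), 2, 2)
    res <- compare_to_naive(s, model)
    res$structured - logZ - res$naive
  })
  expect_lte(mean(diffs), 0.02)
})

test_that("fit tidiers report marginals and model comparison", {
  model <- deconvolution_model(c(0.4, 0.6), n_cells = 30)
  fit <- gibbs_deconvolve(model, n_sweeps = 300, burn_in = 100, seed = 5)
  td <- tidy(fit)
  expect_equal(td$marginal, colMeans(fit$states))
  expect_true(is.finite(glance(fit)$log_posterior))
})
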