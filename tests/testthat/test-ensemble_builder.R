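small_recon <- function() {
  shared("small_recon", function() {
    fx <- fx_small()
    reconstruct_ensemble(
      fx$states[1:20, , drop = FALSE], fx$pairs, fx$params, 60,
      folds_per_cell = 4, seed = 9
    )
  })
}

test_that("reconstruction yields n_cells x folds conformations satisfying states", {
  re <- small_recon()
  fx <- fx_small()
  expect_equal(n_conformations(re), 20 * 4)
  p <- fx$params
  for (c in c(1, 7, 20)) {
    active <- which(fx$states[c, ] == 1)
    for (k in which(re$cell_id == c)) {
      x <- re$coords[, , k]
      for (m in active) {
        expect_lte(
          sqrt(sum((x[fx$pairs$i[m], ] - x[fx$pairs$j[m], ])^2)),
          p$contact_threshold
        )
      }
    }
  }
})

test_that("all-zero states reduce to null-ensemble statistics", {
  p <- desk_params()
  states <- matrix(0L, 10, 2)
  pairs <- tibble::tibble(i = c(5L, 10L), j = c(30L, 50L))
  re <- reconstruct_ensemble(states, pairs, p, 60, folds_per_cell = 10, seed = 3)
  f <- simulated_hic(re)
  fnull <- contact_frequency(ens60a())
  ut <- upper.tri(f)
  expect_gt(cor(f[ut], fnull[ut]), 0.9)
  expect_lt(mean(abs(f[ut] - fnull[ut])), 0.08)
})

test_that("simulated Hi-C equals the tally oracle and ignores cell order", {
  re <- small_recon()
  f <- simulated_hic(re)
  expect_equal(f, t(f))
  # brute-force tally oracle over all folds
  thr <- re$params$contact_threshold
  brute <- matrix(0, 60, 60)
  for (k in seq_len(n_conformations(re))) {
    d <- as.matrix(dist(re$coords[, , k]))
    brute <- brute + re$weights[k] * (d <= thr)
  }
  diag(brute) <- 1
  dimnames(brute) <- NULL
  expect_equal(f, brute, tolerance = 1e-9)
  # permuting conformations leaves the aggregate unchanged
  set.seed(1)
  perm <- sample(n_conformations(re))
  re2 <- re
  re2$coords <- re$coords[, , perm]
  re2$weights <- re$weights[perm]
  re2$log_weights <- re$log_weights[perm]
  expect_equal(simulated_hic(re2), f, tolerance = 1e-12)
})

test_that("aggregation is linear over ensemble unions", {
  eA <- sample_null_ensemble(desk_params(), 15, 8, seed = 1)
  eB <- sample_null_ensemble(desk_params(), 15, 4, seed = 2)
  fA <- contact_frequency(eA)
  fB <- contact_frequency(eB)
  comb <- array(0, dim = c(15, 3, 12))
  comb[, , 1:8] <- eA$coords
  comb[, , 9:12] <- eB$coords
  # equal per-conformation weights: union frequency is the weighted mean
  fU <- contact_frequency(fake_ensemble(comb))
  wA <- ensemble_weights(eA)
  wB <- ensemble_weights(eB)
  # compare against equal-weight tally of both parts
  fA0 <- contact_frequency(fake_ensemble(eA$coords))
  fB0 <- contact_frequency(fake_ensemble(eB$coords))
  expect_equal(fU, (8 * fA0 + 4 * fB0) / 12, tolerance = 1e-12)
  expect_equal(fA, fA0, tolerance = 0.2) # weights are near-uniform post-resampling
})

test_that("hic_pearson matches a hand-computed 5x5 example", {
  sim <- matrix(0, 5, 5)
  meas <- matrix(0, 5, 5)
  sim[1, 4] <- 1; sim[1, 5] <- 2; sim[2, 5] <- 3
  meas[1, 4] <- 2; meas[1, 5] <- 4; meas[2, 5] <- 7
  sim <- sim + t(sim)
  meas <- meas + t(meas)
  # x = (1,2,3), y = (2,4,7): r = 5 / sqrt(2 * 38/3) = 0.9933993
  expect_equal(hic_pearson(sim, meas, exclude_diagonals = 2),
    5 / sqrt(2 * (38 / 3)),
    tolerance = 1e-12
  )
  expect_equal(hic_pearson(meas, meas, exclude_diagonals = 2), 1)
  expect_error(hic_pearson(sim * 0, meas), "Constant")
})

test_that("diagonal exclusion only removes near-diagonal strata", {
  f <- contact_frequency(ens60a())
  g <- contact_frequency(ens60b())
  r0 <- hic_pearson(f, g, exclude_diagonals = 0)
  r2 <- hic_pearson(f, g, exclude_diagonals = 2)
  # both defined; the excluded version drops the strongest shared signal
  expect_true(is.finite(r0) && is.finite(r2))
  expect_gt(r0, r2)
})

test_that("distance correction removes the shared decay", {
  f <- contact_frequency(ens60a())
  g <- contact_frequency(ens60b())
  expect_equal(distance_corrected_pearson(f, f), 1)
  # adding a per-stratum constant changes nothing
  shift <- f
  for (s in seq_len(59)) {
    i <- seq_len(60 - s)
    shift[cbind(i, i + s)] <- shift[cbind(i, i + s)] + s / 100
    shift[cbind(i + s, i)] <- shift[cbind(i, i + s)]
  }
  expect_equal(distance_corrected_pearson(shift, f), 1, tolerance = 1e-9)
  # two independent null ensembles share only the decay: plain Pearson is
  # high, the distance-corrected one collapses
  plain <- hic_pearson(f, g, exclude_diagonals = 0)
  dcp <- distance_corrected_pearson(f, g)
  expect_gt(plain, 0.8)
  expect_lt(abs(dcp), plain - 0.4)
})

test_that("distance matrices match a brute-force loop", {
  p <- desk_params()
  ens <- sample_null_ensemble(p, 10, 3, seed = 7)
  d <- mean_distance_matrix(ens)
  w <- ensemble_weights(ens)
  brute <- matrix(0, 10, 10)
  for (k in 1:3) brute <- brute + w[k] * as.matrix(dist(conformation(ens, k)))
  dimnames(brute) <- NULL
  expect_equal(d, brute, tolerance = 1e-9)
  expect_true(all(diag(d) == 0))
  expect_equal(unname(d[cbind(1:9, 2:10)]), rep(p$bond_length, 9),
    tolerance = 1e-6
  )
  expect_equal(mean_distance_matrix(ens, unit = "angstrom"), d * 10)
})

test_that("per-cell distance matrices subset correctly", {
  re <- small_recon()
  d1 <- cell_distance_matrix(re, 1)
  sel <- which(re$cell_id == 1)
  brute <- matrix(0, 60, 60)
  for (k in sel) brute <- brute + as.matrix(dist(re$coords[, , k])) / length(sel)
  dimnames(brute) <- NULL
  expect_equal(d1, brute, tolerance = 1e-9)
  expect_error(cell_distance_matrix(re, 999), "Unknown cell")
})

test_that("boundary strength has its stated closed forms", {
  # uniform distances: strength 1 wherever defined
  u <- matrix(100, 30, 30)
  diag(u) <- 0
  bs <- boundary_strength(u, window = 5)
  expect_true(all(abs(bs$strength[6:26] - 1) < 1e-12))
  expect_true(all(is.na(bs$strength[1:5])))
  # two-domain toy: within 100, cross 300 -> peak exactly 3 at the junction
  d <- matrix(300, 40, 40)
  d[1:20, 1:20] <- 100
  d[21:40, 21:40] <- 100
  diag(d) <- 0
  bs2 <- boundary_strength(d, window = 6)
  expect_equal(bs2$strength[21], 3)
  expect_equal(which.max(bs2$strength), 21)
  # mirror symmetry: reversing the locus mirrors the profile
  rev_idx <- 40:1
  bs3 <- boundary_strength(d[rev_idx, rev_idx], window = 6)
  for (i in 8:34) {
    expect_equal(bs3$strength[i], bs2$strength[40 - i + 2], tolerance = 1e-12)
  }
  expect_error(boundary_strength(d, window = 1), "at least 2")
  expect_error(boundary_strength(d, window = 25), "half-length")
})

test_that("overlap coefficient handles the stated cases", {
  a <- rbind(c(1, 5), c(2, 8), c(3, 9))
  b <- rbind(c(1, 5), c(2, 8))
  expect_equal(overlap_coefficient(a, b), 1) # subset
  expect_equal(overlap_coefficient(a, a), 1)
  expect_equal(overlap_coefficient(a, rbind(c(7, 9))), 0)
  expect_error(
    overlap_coefficient(a, matrix(numeric(0), ncol = 2)), "empty"
  )
})
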