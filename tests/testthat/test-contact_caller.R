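test_that("quantile normalization fixes points and preserves rank order", {
  locus <- locus60()
  f <- contact_frequency(ens60a())
  hic <- hic_matrix(f, locus, normalized = TRUE)
  out <- quantile_normalize_hic(hic, f)
  expect_equal(out$values, hic$values, tolerance = 1e-12)
  # an arbitrary raw matrix keeps its off-diagonal rank order exactly
  set.seed(8)
  raw <- matrix(0, 60, 60)
  raw[upper.tri(raw)] <- rpois(sum(upper.tri(raw)), 50)
  raw <- raw + t(raw)
  diag(raw) <- 500
  norm <- quantile_normalize_hic(hic_matrix(raw, locus), f)
  ut <- upper.tri(raw)
  # monotone mapping: order is never inverted (ties in the target
  # distribution may merge distinct measured values, never reorder them)
  ord <- order(raw[ut])
  expect_true(all(diff(norm$values[ut][ord]) >= -1e-12))
  # measured ties share one target value
  tied <- which(raw[ut] == raw[ut][1])
  expect_equal(length(unique(norm$values[ut][tied])), 1)
  expect_true(norm$normalized)
})

test_that("quantile normalization matches a hand-worked 4x4 mapping", {
  locus <- locus_spec("chrS", 0, 20000, 5000)
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(5, 1, 4, 2, 8, 6) # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  m <- m + t(m)
  f <- matrix(0, 4, 4)
  f[upper.tri(f)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  f <- f + t(f)
  out <- quantile_normalize_hic(hic_matrix(m, locus), f)
  # ranks of (5,1,4,2,8,6) are (4,1,3,2,6,5) -> sorted targets at those ranks
  expected <- c(0.4, 0.1, 0.3, 0.2, 0.6, 0.5)
  expect_equal(out$values[upper.tri(out$values)], expected, tolerance = 1e-12)
  # ties share the averaged target value
  m2 <- matrix(0, 3, 3)
  m2[upper.tri(m2)] <- c(3, 3, 5)
  m2 <- m2 + t(m2)
  f2 <- matrix(0, 3, 3)
  f2[upper.tri(f2)] <- c(0.1, 0.2, 0.4)
  f2 <- f2 + t(f2)
  out2 <- quantile_normalize_hic(hic_matrix(m2, locus_spec("chrS", 0, 15000, 5000)), f2)
  expect_equal(sort(unique(out2$values[upper.tri(out2$values)])), c(0.15, 0.4))
})

test_that("constant measured matrices are rejected", {
  locus <- locus_spec("chrS", 0, 20000, 5000)
  m <- matrix(1, 4, 4)
  expect_error(
    quantile_normalize_hic(hic_matrix(m, locus), m), "constant"
  )
})

test_that("the BLB null is reproducible and its replicates track the ensemble", {
  n1 <- build_contact_null(ens60a(), n_outer = 200, seed = 5)
  n2 <- build_contact_null(ens60a(), n_outer = 200, seed = 5)
  expect_identical(n1$replicates, n2$replicates)
  expect_warning(build_contact_null(ens60a(), n_outer = 50, seed = 5), "tails")
  # per-distance replicate means converge to the mean ensemble frequency at
  # that distance (within Monte-Carlo error)
  f <- contact_frequency(ens60a())
  for (s in c(5, 20, 40)) {
    i <- seq_len(60 - s)
    target <- mean(f[cbind(i, i + s)])
    reps <- cnull60()$replicates[, s]
    expect_lt(abs(mean(reps) - target), 4 * sd(reps) / sqrt(length(reps)) + 0.01)
  }
})

test_that("extreme measured values give extreme p-values", {
  null <- cnull60()
  f <- null$freq_matrix
  lo <- f * 0
  hi <- pmin(f * 0 + 1, 1)
  p_lo <- null_pair_pvalues(null, lo)
  p_hi <- null_pair_pvalues(null, hi)
  # a value below every replicate is never exceeded-from-above: p ~ 1
  expect_true(all(p_lo[upper.tri(p_lo)] > 0.99))
  # a value at the ceiling: only replicates at 1 can reach it; for a distant
  # pair that never happens, so p hits the add-one floor
  expect_equal(p_hi[1, 60], 1 / (1 + null$n_outer))
})

test_that("self-null calls are calibrated and elevated contacts are recovered", {
  null <- cnull60()
  locus <- locus60()
  m <- contact_frequency(ens60b())
  calls <- call_specific_contacts(hic_matrix(m, locus, normalized = TRUE), null)
  expect_lte(mean(calls$specific), 0.05)
  # monotonicity: raising one entry never increases its p-value
  m2 <- m
  m2[10, 40] <- m2[40, 10] <- min(1, m2[10, 40] * 2)
  calls2 <- call_specific_contacts(hic_matrix(m2, locus, normalized = TRUE), null)
  p1 <- calls$p_value[calls$i == 10 & calls$j == 40]
  p2 <- calls2$p_value[calls2$i == 10 & calls2$j == 40]
  expect_lte(p2, p1)
  # power: pairs elevated to >= 3x the null are recovered
  set.seed(13)
  i0 <- sample(1:35, 12)
  sel <- cbind(i0, i0 + sample(15:24, 12, TRUE))
  m3 <- m
  m3[sel] <- pmin(3 * m3[sel], 0.95)
  m3[sel[, c(2, 1)]] <- m3[sel]
  calls3 <- call_specific_contacts(hic_matrix(m3, locus, normalized = TRUE), null)
  hit <- mapply(
    function(i, j) any(calls3$specific & calls3$i == i & calls3$j == j),
    sel[, 1], sel[, 2]
  )
  expect_gte(mean(hit), 0.9)
})

test_that("near-diagonal strata are excluded from testing", {
  null <- cnull60()
  m <- contact_frequency(ens60b())
  calls <- call_specific_contacts(
    hic_matrix(m, locus60(), normalized = TRUE), null
  )
  expect_gte(min(calls$distance), 3)
  calls0 <- call_specific_contacts(
    hic_matrix(m, locus60(), normalized = TRUE), null,
    exclude_diagonals = 0
  )
  expect_equal(nrow(calls0) - nrow(calls), 59 + 58)
})

test_that("coarse-graining retains round(retention * N) representatives", {
  calls <- synthetic_contact_calls(300, 100, seed = 1)
  coarse <- coarse_grain_contacts(calls, 0.05)
  expect_equal(nrow(retained_contacts(coarse)), 15)
  # retention 1 is the identity
  all_kept <- coarse_grain_contacts(calls, 1)
  expect_equal(nrow(retained_contacts(all_kept)), 300)
  # a single call is retained even when retention * N < 1
  one <- coarse_grain_contacts(calls[1, ], 0.05)
  expect_equal(nrow(retained_contacts(one)), 1)
})

test_that("well-separated groups each yield exactly one representative", {
  calls <- tibble::tibble(
    i = c(10L, 10L, 11L, 60L, 61L),
    j = c(40L, 41L, 40L, 80L, 80L),
    distance = j - i,
    normalized_frequency = c(0.5, 0.6, 0.4, 0.7, 0.9),
    p_value = c(0.001, 0.002, 0.003, 0.004, 0.0001),
    q_value = rep(0.01, 5), specific = TRUE
  )
  coarse <- coarse_grain_contacts(calls, retention_fraction = 0.4) # k = 2
  rep_set <- retained_contacts(coarse)
  expect_equal(nrow(rep_set), 2)
  # brute-force agglomeration: the two Chebyshev-tight groups are the clusters
  expect_setequal(coarse$cluster[1:3], coarse$cluster[1])
  expect_setequal(coarse$cluster[4:5], coarse$cluster[4])
  # representative = smallest p within each cluster
  expect_true(any(rep_set$i == 10 & rep_set$j == 40)) # p 0.001
  expect_true(any(rep_set$i == 61 & rep_set$j == 80)) # p 0.0001
})

test_that("representative tie-breaks use frequency then pair order", {
  calls <- tibble::tibble(
    i = c(10L, 10L), j = c(40L, 41L), distance = j - i,
    normalized_frequency = c(0.5, 0.9),
    p_value = c(0.001, 0.001), q_value = 0.01, specific = TRUE
  )
  rep_set <- retained_contacts(coarse_grain_contacts(calls, 0.5))
  expect_equal(rep_set$j, 41L) # same p, larger frequency wins
})
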