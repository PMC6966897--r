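test_that("constructed geometries yield the expected complexes", {
  p <- desk_params()
  # beads 1, 3, 5 form a 50-nm equilateral triangle; 2, 4 are far away
  xyz <- rbind(
    c(0, 0, 0), c(1000, 0, 0), c(50, 0, 0),
    c(-1000, 0, 0), c(25, 25 * sqrt(3), 0)
  )
  tb <- enumerate_3body(xyz, p)
  expect_equal(nrow(tb), 1)
  expect_equal(c(tb$b1, tb$b2, tb$b3), c(1, 3, 5))
  expect_equal(tb$principal_span, 4 * p$bead_bp)
  expect_equal(tb$minor_span, 2 * p$bead_bp)
  expect_equal(c(tb$anchor1, tb$anchor2), c(1, 5))
  # fewer than 3 bins: empty
  expect_equal(nrow(enumerate_3body(xyz[1:2, , drop = FALSE], p)), 0)
})

test_that("four mutually close beads form one maximal 4-clique", {
  p <- desk_params()
  # beads 1,3,5,7 pairwise within 80 nm; 2,4,6 far
  close <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0), c(20, 20, 30))
  far <- rbind(c(900, 0, 0), c(0, 900, 0), c(0, 0, 900))
  xyz <- rbind(close[1, ], far[1, ], close[2, ], far[2, ], close[3, ], far[3, ], close[4, ])
  mx <- enumerate_maximal(xyz, p)
  expect_equal(nrow(mx), 1)
  expect_equal(mx$size, 4)
  expect_equal(mx$members[[1]], c(1L, 3L, 5L, 7L))
  expect_equal(c(mx$anchor1, mx$anchor2), c(1, 7))
  # the 3-subsets are 3-bodies but none are maximal complexes
  expect_equal(nrow(enumerate_3body(xyz, p)), 4)
})

test_that("clique enumeration matches exhaustive subset search", {
  p <- desk_params()
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(8:15, 1)
    xyz <- matrix(runif(n * 3, -110, 110), n, 3)
    orc <- oracle_cliques(xyz, p$contact_threshold, 2)
    tb <- enumerate_3body(xyz, p)
    got3 <- if (nrow(tb)) {
      sort(paste(tb$b1, tb$b2, tb$b3))
    } else {
      character(0)
    }
    exp3 <- if (nrow(orc$threebody)) {
      sort(apply(orc$threebody, 1, paste, collapse = " "))
    } else {
      character(0)
    }
    expect_identical(got3, exp3)
    mx <- enumerate_maximal(xyz, p)
    gotm <- sort(vapply(mx$members, paste, "", collapse = " "))
    expm <- sort(vapply(orc$maximal, paste, "", collapse = " "))
    expect_identical(gotm, expm)
    # no maximal complex is extendable (asserted against the oracle adjacency)
    if (nrow(mx)) {
      expect_true(all(mx$size >= 3))
      expect_true(all(mx$principal_span >= mx$minor_span))
    }
  }
})

mbnull_small <- function() {
  shared("mbnull_small", function() {
    build_manybody_null(ens60a(),
      n_replicates = 500, mode = "3body",
      params = desk_params(), seed = 6
    )
  })
}

test_that("the stratified null is reproducible and tracks direct tallies", {
  n1 <- mbnull_small()
  n2 <- build_manybody_null(ens60a(),
    n_replicates = 500, mode = "3body",
    params = desk_params(), seed = 6
  )
  expect_identical(n1$strata, n2$strata)
  # the pooled replicate mean of a stratum equals the mean tallied frequency
  # of its complexes (bootstrap resampling is unbiased for the tally)
  tal <- n1$tally
  st <- names(sort(table(tal$stratum), decreasing = TRUE))[1]
  rows <- tal[tal$stratum == st, ]
  pool <- n1$strata[[st]]
  pooled_mean <- sum(pool$values * pool$weights) / sum(pool$weights)
  expect_lt(abs(pooled_mean - mean(rows$frequency)), 0.01)
})

test_that("self-null many-body calls stay within the FDR budget", {
  calls <- call_specific_manybodies(ens60b(), mbnull_small(),
    params = desk_params()
  )
  expect_lte(mean(calls$specific), 0.05)
  # a complex absent from the tested ensemble is simply never tested
  expect_true(all(calls$frequency > 0))
})

test_that("planted triples in the fixture are called specific", {
  fx <- fx_small()
  null60 <- mbnull_small()
  calls <- suppressMessages(
    call_specific_manybodies(fx$ensemble, null60, params = fx$params)
  )
  spec <- calls[calls$specific, ]
  tri <- fx$planted_triples
  found <- vapply(seq_len(nrow(tri)), function(r) {
    paste(sort(c(tri$b1[r], tri$b2[r], tri$b3[r])), collapse = "_") %in%
      spec$signature
  }, logical(1))
  expect_gte(mean(found), 2 / 3)
})

test_that("the functional landscape matches a hand tally", {
  locus <- locus_spec("chrS", 0, 100 * 5000)
  # bins 10, 30 are SE; bin 50 is P; bin 70 is E
  ann <- tibble::tibble(
    start = c(45000, 145000, 245000, 345000),
    end = c(50000, 150000, 250000, 350000),
    label = c("SE", "SE", "P", "E")
  )
  ann <- structure(ann, locus = locus, class = c("annotation_track", class(ann)))
  calls <- tibble::tibble(
    signature = c("10_30_50", "10_20_30", "5_6_7", "10_50_70", "20_40_60"),
    size_class = "3",
    anchor1 = c(10L, 10L, 5L, 10L, 20L), anchor2 = c(50L, 30L, 7L, 70L, 60L),
    principal_span = 1, minor_span = 1, frequency = 0.5,
    p_value = 0.01, q_value = c(0.01, 0.01, 0.01, 0.2, 0.2),
    specific = c(TRUE, TRUE, TRUE, FALSE, FALSE), pooled = FALSE
  )
  ls <- functional_landscape(calls, ann)
  spec <- ls$fractions[ls$fractions$group == "specific", ]
  # specific: {SE,SE,P} (2 SE + P), {SE,none,SE}, {none x3}
  expect_equal(spec$no_functional, 1 / 3)
  expect_equal(spec$ge2_SE_with_P, 1 / 3)
  expect_equal(spec$ge3_SE, 0)
  nonspec <- ls$fractions[ls$fractions$group == "non-specific", ]
  expect_equal(nonspec$no_functional, 1 / 2)
  # anchor pair labels: specific anchors (10,50)=SE-P, (10,30)=SE-SE,
  # (5,7)=none-none
  ap <- ls$anchor_pairs[ls$anchor_pairs$group == "specific", ]
  expect_setequal(ap$pair, c("P-SE", "SE-SE", "none-none"))
  expect_true(all(abs(ap$proportion - 1 / 3) < 1e-12))
  # all-none annotation: 100% no association
  ann0 <- structure(ann[0, ], locus = locus, class = class(ann))
  ls0 <- functional_landscape(calls, ann0)
  expect_true(all(ls0$fractions$no_functional == 1))
})

test_that("coverage fractions and the permutation test behave", {
  clusters <- list(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L), c(2L, 3L, 9L))
  calls <- tibble::tibble(
    signature = c("1_2_3", "2_3_9", "1_2_9"), size_class = "3",
    anchor1 = c(1L, 2L, 1L), anchor2 = c(3L, 9L, 9L),
    principal_span = c(10000, 35000, 40000),
    minor_span = c(5000, 5000, 5000),
    frequency = 0.5, p_value = 0.01, q_value = 0.01,
    specific = c(TRUE, FALSE, FALSE), pooled = FALSE
  )
  cov <- coverage_fraction(calls, clusters)
  expect_equal(cov$coverage, c(2 / 3, 1 / 3, 0))
  # anchors-only coverage uses the two anchors
  cov2 <- coverage_fraction(calls, clusters, anchors_only = TRUE)
  expect_equal(cov2$coverage[1], 2 / 3)
  expect_error(coverage_fraction(calls, list()), "No clusters")
  # calibration: when specific labels carry no coverage signal, the
  # permutation p-value is not extreme
  set.seed(2)
  big <- tibble::tibble(
    signature = paste0(1:60, "_x"), size_class = "3",
    anchor1 = 1L, anchor2 = 2L,
    principal_span = rep(c(10000, 20000, 30000), each = 20),
    minor_span = 5000,
    frequency = 0.5, p_value = 0.01, q_value = 0.01,
    specific = rep(c(TRUE, FALSE), 30), pooled = FALSE,
    coverage = runif(60)
  )
  res <- coverage_permutation_test(big, n_permutations = 300, seed = 3)
  expect_gt(res$p_value, 0.05)
  expect_lte(res$observed_proportion, 1)
})

test_that("principal-loop heatmaps match a brute-force re-tally", {
  p <- desk_params()
  ens <- sample_null_ensemble(p, 30, 10, seed = 14)
  for (k in c("3", "4")) {
    h <- principal_loop_heatmap(ens, k, params = p)
    expect_equal(h, t(h))
    brute <- matrix(0, 30, 30)
    for (c in 1:10) {
      mx <- enumerate_maximal(ens$coords[, , c], p)
      if (nrow(mx) == 0) next
      mx <- mx[chromfold:::size_class(mx$size) == k, , drop = FALSE]
      if (nrow(mx) == 0) next
      anch <- unique(cbind(mx$anchor1, mx$anchor2))
      brute[anch] <- brute[anch] + 1 / 10
    }
    brute <- brute + t(brute) - diag(diag(brute))
    expect_equal(h, brute, tolerance = 1e-12)
    # row sums equal per-bin anchor participation
    expect_equal(rowSums(h), colSums(h))
  }
})
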