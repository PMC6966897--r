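test_that("confinement radius follows the constant-density closed form", {
  p <- polymer_params(bp_density = 3 / (4 * pi))
  # L_bp / bp_density == 4*pi/3 gives a unit sphere
  expect_equal(confinement_radius_for(locus_spec("c", 0, 1), p), 1)
  # doubling the length scales the radius by 2^(1/3)
  r1 <- confinement_radius_for(locus_spec("c", 0, 5e5), polymer_params())
  r2 <- confinement_radius_for(locus_spec("c", 0, 1e6), polymer_params())
  expect_equal(r2 / r1, 2^(1 / 3))
  # hand formula on a 500-KB locus with density chosen for ~400 nm
  rho <- 3 * 5e5 / (4 * pi * 400^3)
  p4 <- polymer_params(bp_density = rho)
  expect_equal(confinement_radius_for(locus_spec("c", 0, 5e5), p4), 400)
})

test_that("parameter invariants are enforced", {
  expect_error(polymer_params(contact_threshold = 10), "exceed")
  expect_error(polymer_params(bond_length = 5), "at least")
})

test_that("a two-bead chain sits exactly one bond apart with finite weight", {
  p <- desk_params()
  conf <- grow_chain(p, 2, seed = 3)
  expect_equal(sqrt(sum((conf$coords[1, ] - conf$coords[2, ])^2)),
    p$bond_length,
    tolerance = 1e-9
  )
  expect_true(is.finite(conf$log_weight))
})

test_that("required contacts are satisfied in every grown chain", {
  p <- desk_params()
  for (s in 1:5) {
    conf <- grow_chain(p, 3, required_contacts = cbind(1, 3), seed = s)
    expect_lte(
      sqrt(sum((conf$coords[1, ] - conf$coords[3, ])^2)),
      p$contact_threshold
    )
  }
})

test_that("every emitted conformation is self-avoiding, bonded and confined", {
  p <- desk_params()
  ens <- ens60a()
  for (k in c(1, 500, 1200)) {
    x <- conformation(ens, k)
    d <- as.matrix(dist(x))
    bonds <- d[cbind(seq_len(59), 2:60)]
    expect_equal(max(abs(bonds - p$bond_length)), 0, tolerance = 1e-6)
    nonadj <- d + diag(Inf, 60)
    nonadj[cbind(seq_len(59), 2:60)] <- Inf
    nonadj[cbind(2:60, seq_len(59))] <- Inf
    expect_gte(min(nonadj), p$fiber_diameter)
    expect_lte(max(sqrt(rowSums(x^2))), ens$confinement_radius + 1e-9)
  }
})

test_that("ensembles are bit-identical under a fixed seed", {
  p <- desk_params()
  e1 <- sample_null_ensemble(p, 20, 50, seed = 9)
  e2 <- sample_null_ensemble(p, 20, 50, seed = 9)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$log_weights, e2$log_weights)
  e3 <- sample_null_ensemble(p, 20, 50, seed = 10)
  expect_false(identical(e1$coords, e3$coords))
})

test_that("contact frequency decays with genomic distance (Spearman <= 0)", {
  f <- contact_frequency(ens60a())
  by_dist <- vapply(seq_len(59), function(s) {
    i <- seq_len(60 - s)
    mean(f[cbind(i, i + s)])
  }, numeric(1))
  expect_lte(cor(seq_len(59), by_dist, method = "spearman"), 0)
})

test_that("contact_frequency equals a brute-force tally", {
  p <- desk_params()
  ens <- sample_null_ensemble(p, 12, 10, seed = 21)
  f <- contact_frequency(ens)
  w <- ensemble_weights(ens)
  brute <- matrix(0, 12, 12)
  for (k in 1:10) {
    d <- as.matrix(dist(conformation(ens, k)))
    brute <- brute + w[k] * (d <= p$contact_threshold)
  }
  diag(brute) <- 1
  dimnames(brute) <- NULL
  expect_equal(f, brute, tolerance = 1e-12)
  # bonded neighbours are always in contact; single conformation is binary
  expect_true(all(f[cbind(seq_len(11), 2:12)] == 1))
  single <- fake_ensemble(ens$coords[, , 1, drop = FALSE], p)
  expect_true(all(contact_frequency(single) %in% c(0, 1)))
})

test_that("constrained ensembles satisfy every constraint with probability 1", {
  p <- desk_params()
  ens <- sample_constrained_ensemble(
    p, 40, rbind(c(1, 40), c(10, 25)), 60,
    seed = 4
  )
  for (k in seq_len(60)) {
    x <- conformation(ens, k)
    expect_lte(sqrt(sum((x[1, ] - x[40, ])^2)), p$contact_threshold)
    expect_lte(sqrt(sum((x[10, ] - x[25, ])^2)), p$contact_threshold)
  }
})

test_that("an empty contact state reduces to null sampling", {
  p <- desk_params()
  e1 <- sample_constrained_ensemble(p, 15, NULL, 30, seed = 6)
  e2 <- sample_null_ensemble(p, 15, 30, seed = 6)
  expect_identical(e1$coords, e2$coords)
  expect_equal(e1$kind, "null")
})

test_that("geometrically unsatisfiable states raise InfeasibleState", {
  # a bond longer than the contact threshold makes adjacent pairs impossible
  p <- polymer_params(bond_length = 100)
  expect_error(
    sample_constrained_ensemble(p, 60, cbind(5, 6), 10, seed = 1),
    class = "chromfold_infeasible_state"
  )
  pre <- feasibility_precheck(p, 60, cbind(5, 6))
  expect_false(pre$feasible)
})

test_that("SMC frequencies match a rejection-sampling oracle on short chains", {
  # scaled-down companion of the acceptance check: 6 beads, wider sphere
  p <- polymer_params(bp_density = 3 * 3e4 / (4 * pi * 100^3), bond_length = 45)
  R <- confinement_radius_for(6, p)
  set.seed(31)
  nprop <- 60000
  rdirs <- function(n) {
    z <- 2 * runif(n) - 1
    ph <- 2 * pi * runif(n)
    s <- sqrt(1 - z^2)
    cbind(s * cos(ph), s * sin(ph), z)
  }
  x <- array(0, c(nprop, 6, 3))
  x[, 1, ] <- rdirs(nprop) * (R * runif(nprop)^(1 / 3))
  for (t in 2:6) x[, t, ] <- x[, t - 1, ] + p$bond_length * rdirs(nprop)
  ok <- rep(TRUE, nprop)
  for (t in 1:6) ok <- ok & sqrt(rowSums(x[, t, ]^2)) <= R
  for (a in 1:4) {
    for (b in (a + 2):6) {
      ok <- ok & sqrt(rowSums((x[, a, ] - x[, b, ])^2)) >= p$fiber_diameter
    }
  }
  xa <- x[ok, , ]
  ens <- sample_null_ensemble(p, 6, 4000, seed = 32)
  f <- contact_frequency(ens)
  w <- ensemble_weights(ens)
  for (a in 1:4) {
    for (b in (a + 2):6) {
      fo <- mean(sqrt(rowSums((xa[, a, ] - xa[, b, ])^2)) <= p$contact_threshold)
      se_o <- sqrt(fo * (1 - fo) / sum(ok))
      ind <- (sqrt(colSums((ens$coords[a, , ] - ens$coords[b, , ])^2)) <=
        p$contact_threshold) * 1
      m <- sum(w * ind)
      se_s <- sqrt(sum(w^2 * (ind - m)^2))
      expect_lt(abs(fo - f[a, b]), 3 * sqrt(se_o^2 + se_s^2) + 1e-9)
    }
  }
})
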