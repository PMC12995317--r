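test_that("enumeration reproduces closed forms and exchangeability", {
  m2 <- block_spin(2, matrix(1))
  expect_equal(enumerate_pair_correlations(m2)[1, 2], tanh(0.5),
               tolerance = 1e-14)
  expect_equal(enumerate_pair_correlations(m2)[1, 2],
               (exp(1) - 1) / (exp(1) + 1), tolerance = 1e-14)

  m <- block_spin(c(3, 2), matrix(c(0.7, 0.2, 0.2, 0.5), 2, 2))
  E <- enumerate_pair_correlations(m)
  # block-constant by exchangeability
  expect_lt(max(abs(c(E[1, 2] - E[2, 3], E[1, 2] - E[1, 3]))), 1e-14)
  expect_lt(abs(E[4, 5] - E[4, 5]), 1e-14)
  expect_lt(max(abs(E[1:3, 4:5] - E[1, 4])), 1e-14)

  # diagonal coupling factorises the measure: zero cross-group correlation
  mi <- block_spin(c(2, 2), 0.5 * diag(2))
  Ei <- enumerate_pair_correlations(mi)
  expect_lt(max(abs(Ei[1:2, 3:4])), 1e-14)

  expect_error(enumerate_pair_correlations(block_spin(c(9, 9), 0.5 * diag(2))),
               "N <= 16")
})

test_that("oracle triangle: sufficient statistic = enumeration = quadrature", {
  models <- list(
    block_spin(4, matrix(0.5)),                                   # M=1 high
    block_spin(6, matrix(0.9)),                                   # M=1 near-critical high
    block_spin(5, matrix(1.6)),                                   # M=1 low
    block_spin(c(2, 2), 0.5 * diag(2)),                           # M=2 independent
    block_spin(c(3, 3), matrix(c(0.6, 0.1, 0.1, 0.4), 2, 2)),     # M=2 high
    block_spin(c(2, 4), matrix(c(0.7, -0.2, -0.2, 0.5), 2, 2)),   # M=2 high antag.
    block_spin(c(3, 3), matrix(c(1.5, -0.1, -0.1, 1.5), 2, 2)),   # M=2 low
    block_spin(c(4, 2), matrix(c(1.4, 0.2, 0.2, 1.2), 2, 2))      # M=2 low aligned
  )
  for (m in models) {
    E_enum <- enumerate_pair_correlations(m)
    E_suff <- sufficient_pair_correlations(m)
    expect_lt(max(abs(E_enum - E_suff)), 1e-12)
    # one same-group and (when M = 2) one cross-group pair via quadrature
    i2 <- which(m$labels == m$labels[1])[2]
    expect_equal(definetti_pair_correlation(m, 1, i2), E_enum[1, i2],
                 tolerance = 1e-6)
    if (m$M == 2) {
      j <- which(m$labels == 2)[1]
      expect_equal(definetti_pair_correlation(m, 1, j), E_enum[1, j],
                   tolerance = 1e-6)
    }
  }
})

test_that("relative entropy: value, conventions and the quadratic bound", {
  expect_equal(relative_entropy(0.5, 0.5), 0)
  expect_equal(relative_entropy(0.5, 0.25),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-14)
  expect_identical(relative_entropy(0.5, 0), Inf)
  expect_equal(relative_entropy(0, 0.5), log(2))   # 0 log 0 = 0
  expect_error(relative_entropy(1.2, 0.5), "two-point")

  # H(nu | theta) >= eps^2 / 8 whenever the means differ by at least eps
  ps <- seq(0.02, 0.98, length.out = 40)
  for (p in ps) {
    for (q in ps) {
      eps <- abs(2 * p - 2 * q)   # mean gap: |(1-2p) - (1-2q)|
      if (eps > 0) {
        expect_gte(relative_entropy(p, q), eps^2 / 8 - 1e-14)
      }
    }
  }
})

test_that("the quadratic bound is off by exactly a factor 4 at the fair law", {
  # second-order expansion: at theta = (1/2,1/2) and mean gap eps -> 0,
  # H approaches eps^2/2, i.e. 4 times the bound
  ratio <- sapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    relative_entropy(0.5 + eps / 2, 0.5) / (eps^2 / 8)
  })
  expect_equal(ratio[3], 4, tolerance = 1e-3)
  expect_true(all(diff(ratio) < 0))   # monotone approach from above
})

test_that("Sanov-type bound dominates simulated deviation frequencies", {
  expect_equal(sanov_upper_bound(1, 1e-9), 4, tolerance = 1e-6)
  expect_lt(sanov_upper_bound(1e6, 0.1), 1e-300)

  set.seed(55)
  p_plus <- 0.7           # law of a +-1 product with mean 0.4
  for (n in c(100, 1000)) {
    reps <- 2000
    means <- colMeans(matrix(sample(c(1, -1), n * reps, TRUE,
                                    prob = c(p_plus, 1 - p_plus)), n, reps))
    for (eps in c(0.1, 0.2)) {
      emp <- mean(abs(means - 0.4) >= eps)
      expect_lte(emp, sanov_upper_bound(n, eps))
    }
  }
})

test_that("recovery experiments are seeded, label-invariant and summarised", {
  m <- low_temp_model(c(6, 6))
  r0 <- recovery_experiment(m, n = 100, reps = 0)
  expect_equal(r0$reps, 0L)
  expect_true(is.na(r0$rate))

  r1 <- recovery_experiment(m, n = 3000, reps = 5, seed = 42)
  r2 <- recovery_experiment(m, n = 3000, reps = 5, seed = 42)
  expect_identical(r1$exact_match, r2$exact_match)
  expect_identical(r1$statuses, r2$statuses)
  expect_gte(r1$rate, 0.8)

  # label-invariance of the partition comparison
  expect_true(blockspin:::.same_partition(c(2, 2, 1, 1), c(1, 1, 2, 2)))
  expect_false(blockspin:::.same_partition(c(1, 2, 1, 2), c(1, 1, 2, 2)))
  expect_false(blockspin:::.same_partition(c(1, NA, 2, 2), c(1, 1, 2, 2)))
})
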