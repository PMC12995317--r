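test_that("free energy vanishes at the origin and is even", {
  models <- list(three_party_model(), low_temp_model(), block_spin(4, matrix(2)))
  set.seed(11)
  for (m in models) {
    expect_equal(free_energy(m, rep(0, m$M)), 0)
    for (rep in 1:5) {
      x <- rnorm(m$M)
      expect_equal(free_energy(m, x), free_energy(m, -x), tolerance = 1e-13)
    }
  }
})

test_that("analytic derivatives match central differences", {
  set.seed(21)
  models <- list(three_party_model(), low_temp_model(),
                 block_spin(c(3, 4), matrix(c(0.7, 0.2, 0.2, 0.5), 2, 2)))
  for (m in models) {
    f <- function(x) free_energy(m, x)
    for (rep in 1:4) {
      x <- rnorm(m$M)
      d <- free_energy_derivatives(m, x)
      expect_equal(d$gradient, num_gradient(f, x), tolerance = 1e-6)
      expect_equal(d$hessian, num_hessian(f, x), tolerance = 1e-5)
    }
  }
})

test_that("Hessian at the origin equals H = J^-1 - I exactly", {
  m <- three_party_model()
  d <- free_energy_derivatives(m, rep(0, 3))
  expect_equal(d$gradient, rep(0, 3))
  expect_equal(d$hessian, solve(m$J) - diag(3))
  expect_identical(d$hessian, pair_limit_high(m)$H)
})

test_that("high-temperature Hessian is positive definite everywhere sampled", {
  m <- three_party_model()
  set.seed(5)
  for (rep in 1:20) {
    H <- free_energy_derivatives(m, rnorm(3, sd = 2))$hessian
    expect_gt(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("minima: unique at origin in high temperature, +-beta m* for Curie-Weiss", {
  Lh <- find_minima(three_party_model())
  expect_equal(Lh$K, 1L)
  expect_equal(as.vector(Lh$minima), rep(0, 3), tolerance = 1e-8)

  Lh1 <- find_minima(block_spin(4, matrix(0.5)))
  expect_equal(Lh1$K, 1L)
  expect_equal(as.vector(Lh1$minima), 0, tolerance = 1e-8)

  beta <- 2
  mstar <- cw_magnetization(beta)
  L <- find_minima(block_spin(4, matrix(beta)))
  expect_equal(L$K, 2L)
  expect_equal(sort(as.vector(L$minima)), c(-beta * mstar, beta * mstar),
               tolerance = 1e-8)
  expect_equal(as.vector(L$gram), mstar^2, tolerance = 1e-8)
})

test_that("landscape is closed under sign flip with equal minimum values", {
  L <- find_minima(low_temp_model())
  expect_equal(L$K, 2L)
  flip <- -L$minima[1, ]
  expect_true(any(apply(L$minima, 1, function(z) max(abs(z - flip)) < 1e-8)))
  fv <- free_energy(low_temp_model(), L$minima)
  expect_lt(diff(range(fv)), 1e-10)
})

test_that("Z vectors: gram symmetric, bounded, and detects non-identifiability", {
  L <- find_minima(low_temp_model())
  expect_true(L$identifiable)
  expect_equal(L$gram, t(L$gram))
  expect_true(all(abs(L$gram) <= 1))
  # aligned coupling: both groups share the tanh profile at every minimum
  aligned <- block_spin(c(10, 10), matrix(c(1.5, 0.1, 0.1, 1.5), 2, 2))
  La <- find_minima(aligned)
  expect_false(La$identifiable)
  expect_error(level_spec(La), "identifiable")
})

test_that("gram matrix approaches exact correlations in low temperature", {
  m <- low_temp_model(c(150, 150))   # N = 300
  L <- find_minima(m)
  ec <- sufficient_pair_correlations(m, by_group = TRUE)
  # Laplace error decays like polylog(N)/N
  expect_lt(max(abs(ec - L$gram)), 0.05)
})

test_that("off-diagonals of an inverse s.p.d. matrix stay below max diagonal", {
  set.seed(99)
  for (rep in 1:500) {
    A <- solve(random_spd(sample(2:5, 1)))
    d <- diag(A)
    for (l in seq_len(nrow(A) - 1)) {
      for (mm in seq(l + 1, nrow(A))) {
        expect_lt(A[l, mm], max(d[l], d[mm]))
      }
    }
  }
})

test_that("separation constants match an exhaustive pair scan", {
  set.seed(31)
  for (rep in 1:20) {
    A <- solve(random_spd(4))
    sep <- separation_constants(A)
    d <- diag(A)
    eta_ref <- Inf; xi_ref <- Inf
    for (l in 1:3) {
      for (mm in (l + 1):4) {
        eta_ref <- min(eta_ref, max(d[l], d[mm]) - A[l, mm])
        if (abs(d[l] - d[mm]) > 1e-9) xi_ref <- min(xi_ref, abs(d[l] - d[mm]))
      }
    }
    expect_equal(sep$eta, eta_ref)
    expect_equal(sep$xi, xi_ref)
    expect_equal(sep$delta, min(eta_ref, xi_ref))
  }
})

test_that("equal diagonals give xi = +Inf and delta = eta", {
  sep <- separation_constants(diag(2))
  expect_equal(sep$eta, 1)
  expect_identical(sep$xi, Inf)
  expect_equal(sep$delta, 1)
  sep1 <- separation_constants(matrix(5))
  expect_identical(sep1$delta, Inf)
})

test_that("failure bound arithmetic, monotone tail and vacuous head", {
  expect_equal(failure_bound("high", N = 10, n = 0, sep = 1), 100)
  # beyond the turning point the log-derivative 2/(n+1) - c is negative
  delta <- 1.0344827586
  N <- 6
  c0 <- (delta / (8 * N))^2 / 8
  ns <- ceiling(2 / c0) * c(1, 2, 4, 8, 16)
  b <- failure_bound("high", N, ns, delta)
  expect_true(all(diff(b) < 0))
  expect_lt(failure_bound("high", N, ceiling(200 / c0), delta), 1e-20)
})

test_that("min_observations is minimal and scales like N^2 at fixed delta", {
  ns <- min_observations("low", N = 20, sep = 1.5865, eps = 0.2)
  expect_lte(failure_bound("low", 20, ns, 1.5865), 0.2)
  expect_gt(failure_bound("low", 20, ns - 1, 1.5865), 0.2)

  # doubling N quadruples n* up to slowly-varying log factors
  n1 <- min_observations("high", N = 1000, sep = 1, eps = 0.01)
  n2 <- min_observations("high", N = 2000, sep = 1, eps = 0.01)
  expect_gt(n2 / n1, 3.9)
  expect_lt(n2 / n1, 4.5)
})

test_that("level specs have decreasing non-overlapping windows", {
  th <- pair_limit_high(three_party_model())
  sp <- level_spec(th)
  expect_equal(sp$regime, "high")
  expect_equal(length(sp$levels), 3L)
  expect_true(all(diff(sp$levels) < 0))
  expect_true(all(sp$levels[-3] - sp$halfwidth > sp$levels[-1] + sp$halfwidth))
  # low temperature: symmetric two-group model shares one level
  spl <- level_spec(find_minima(low_temp_model()))
  expect_equal(spl$regime, "low")
  expect_equal(length(spl$levels), 1L)
  expect_equal(sort(spl$groups_at_level[[1]]), 1:2)
  # M = 1: everything-window
  sp1 <- level_spec(pair_limit_high(block_spin(5, matrix(0.5))))
  expect_identical(sp1$halfwidth, Inf)
})
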