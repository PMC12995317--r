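test_that("empirical correlations match hand computation", {
  x <- rbind(c(1, 1, -1), c(1, -1, -1))
  C <- empirical_correlations(x)
  expect_equal(C[1, 2], 0)
  expect_equal(C[1, 3], -1)
  expect_equal(C[2, 3], 0)
  expect_equal(attr(C, "n"), 2)
  expect_equal(unclass(C), t(unclass(C)))

  ones <- matrix(1, 1, 4)
  expect_true(all(empirical_correlations(ones) == 1))
  flip <- rbind(c(1, -1, 1), c(-1, 1, -1))
  expect_true(all(abs(empirical_correlations(flip)) == 1))
  expect_error(empirical_correlations(matrix(c(1, 0), 1)), "-1 or \\+1")
})

# synthetic block-constant correlation matrix at prescribed levels
block_corr <- function(sizes, within, cross) {
  lab <- rep(seq_along(sizes), sizes)
  C <- cross[lab, lab, drop = FALSE]
  for (l in seq_along(sizes)) {
    idx <- lab == l
    C[idx, idx] <- within[l]
  }
  diag(C) <- 1
  C
}

test_that("window recursion recovers a planted 3-block structure exactly", {
  sizes <- c(5, 4, 3)
  within <- c(0.30, 0.20, 0.12)
  cross <- matrix(0.02, 3, 3)
  C <- block_corr(sizes, within, cross)
  spec <- list(levels = within, halfwidth = 0.02)
  res <- identify_groups(C, spec)
  expect_equal(res$status, "success")
  expect_equal(res$membership, rep(1:3, sizes))
  expect_equal(res$class_level, 1:3)
  # windows never overlap and every pair sits in at most one
  pw <- res$diagnostics$pair_window
  expect_true(all(table(pw$window) > 0))
})

test_that("exclusion set: cross pairs at an interleaved level are ignored", {
  # cross level between the two within levels, as happens for real couplings
  sizes <- c(4, 4)
  C <- block_corr(sizes, within = c(0.5, 0.1),
                  cross = matrix(0.3, 2, 2))
  spec <- list(levels = c(0.5, 0.3, 0.1), halfwidth = 0.05)
  res <- identify_groups(C, spec)
  expect_equal(res$status, "success")
  expect_equal(res$membership, rep(c(1, 2), each = 4))
  # the middle window received no edges: all its pairs touch class 1
  expect_equal(res$class_level, c(1L, 3L))
})

test_that("single-level spec groups the whole population", {
  C <- block_corr(6, within = 0.4, cross = matrix(0, 1, 1))
  res <- identify_groups(C, list(levels = 0.4, halfwidth = 0.1))
  expect_equal(res$status, "success")
  expect_equal(length(res$classes), 1L)
  expect_equal(res$classes[[1]], 1:6)
})

test_that("atypical samples are reported, not raised", {
  # individual 5's correlations fall in no window
  C <- block_corr(c(4, 1), within = c(0.4, 0), cross = matrix(-0.5, 2, 2))
  res <- identify_groups(C, list(levels = 0.4, halfwidth = 0.05))
  expect_equal(res$status, "inconsistent_sample")
  expect_equal(res$diagnostics$unassigned, 5L)

  # one within-pair pushed outside every window: its class is inconsistent
  C2 <- block_corr(4, within = 0.4, cross = matrix(0, 1, 1))
  C2[1, 2] <- C2[2, 1] <- 0.2
  res2 <- identify_groups(C2, list(levels = 0.4, halfwidth = 0.05))
  expect_equal(res2$status, "inconsistent_sample")
})

test_that("overlapping windows are rejected as an invalid spec", {
  C <- block_corr(4, within = 0.4, cross = matrix(0, 1, 1))
  expect_error(identify_groups(C, list(levels = c(0.4, 0.35), halfwidth = 0.05)),
               "overlap")
})

test_that("population-limit recovery for the exactly-certified regime", {
  # diagonal coupling: groups independent, correlations exactly block-constant,
  # and the finite-N values sit well inside the theoretical windows
  m <- block_spin(c(60, 40), diag(c(0.4, 0.2)))
  th <- pair_limit_high(m)
  spec <- level_spec(th)
  EC <- sufficient_pair_correlations(m)
  # certify the window condition before asserting recovery
  lab <- m$labels
  for (l in 1:2) {
    idx <- which(lab == l)
    lev <- th$limit_matrix[l, l] / m$N
    expect_lt(abs(EC[idx[1], idx[2]] - lev), spec$halfwidth / 2)
  }
  res <- identify_groups(EC, spec)
  expect_equal(res$status, "success")
  expect_true(blockspin:::.same_partition(res$membership, lab))
})

test_that("low-temperature recovery from exact correlations at N = 20", {
  m <- low_temp_model(c(10, 10))
  spec <- level_spec(find_minima(m))
  EC <- sufficient_pair_correlations(m)
  res <- identify_groups(EC, spec)
  expect_equal(res$status, "success")
  expect_true(blockspin:::.same_partition(res$membership, m$labels))
})

test_that("recovery is equivariant under relabelling of individuals", {
  m <- low_temp_model(c(6, 6))
  spec <- level_spec(find_minima(m))
  x <- draw_sample(m, 4000, seed = 17)
  set.seed(99)
  perm <- sample(seq_len(m$N))
  res <- identify_groups(empirical_correlations(x), spec)
  resp <- identify_groups(empirical_correlations(unclass(x)[, perm]), spec)
  expect_equal(res$status, "success")
  expect_true(blockspin:::.same_partition(resp$membership[order(perm)],
                                          res$membership))
})

test_that("class labelling follows levels, then sizes, then flags ambiguity", {
  sizes <- c(5, 4, 3)
  C <- block_corr(sizes, within = c(0.3, 0.2, 0.12), cross = matrix(0.02, 3, 3))
  spec <- list(levels = c(0.3, 0.2, 0.12), halfwidth = 0.02,
               groups_at_level = list(1L, 2L, 3L))
  res <- label_classes(identify_groups(C, spec), spec, sizes = sizes)
  expect_equal(res$labels_hat, 1:3)
  expect_false(any(res$label_ambiguous))

  # two groups at one level, distinguishable by size
  C2 <- block_corr(c(4, 6), within = c(0.3, 0.3), cross = matrix(0, 2, 2))
  spec2 <- list(levels = 0.3, halfwidth = 0.02, groups_at_level = list(c(1L, 2L)))
  res2 <- label_classes(identify_groups(C2, spec2), spec2, sizes = c(4, 6))
  expect_equal(sort(res2$labels_hat), 1:2)
  expect_false(any(res2$label_ambiguous))

  # equal level, equal sizes: label-unidentifiable, flagged
  C3 <- block_corr(c(5, 5), within = c(0.3, 0.3), cross = matrix(0, 2, 2))
  spec3 <- list(levels = 0.3, halfwidth = 0.02, groups_at_level = list(c(1L, 2L)))
  res3 <- label_classes(identify_groups(C3, spec3), spec3, sizes = c(5, 5))
  expect_true(all(res3$label_ambiguous))

  # class count mismatch is an upstream failure
  spec4 <- list(levels = 0.3, halfwidth = 0.02,
                groups_at_level = list(c(1L, 2L, 3L)))
  expect_error(label_classes(identify_groups(C3, spec4), spec4,
                             sizes = c(5, 5, 5)),
               "upstream")
})

test_that("agnostic banding matches window detection on clean structure", {
  sizes <- c(5, 4, 3)
  C <- block_corr(sizes, within = c(0.3, 0.2, 0.12), cross = matrix(0.02, 3, 3))
  res <- identify_groups_agnostic(C)
  expect_equal(res$status, "success")
  expect_equal(res$membership, rep(1:3, sizes))
})

test_that("agnostic mode: constant correlations give one class", {
  C <- block_corr(8, within = 0.25, cross = matrix(0, 1, 1))
  res <- identify_groups_agnostic(C)
  expect_equal(length(res$classes), 1L)
  expect_equal(res$classes[[1]], 1:8)
})

test_that("agnostic mode calls independent noise a single class", {
  set.seed(1234)
  n <- 4000
  X <- matrix(sample(c(-1, 1), n * 12, replace = TRUE), n, 12)
  res <- identify_groups_agnostic(empirical_correlations(X))
  expect_equal(res$status, "success")
  expect_equal(length(res$classes), 1L)
})

test_that("detect_communities wires sample, theory and labels together", {
  m <- low_temp_model(c(8, 8))
  x <- draw_sample(m, 5000, seed = 3)
  res <- detect_communities(x, m)
  expect_equal(res$status, "success")
  expect_true(blockspin:::.same_partition(res$membership, m$labels))
  expect_true(all(res$label_ambiguous))  # symmetric groups: names unidentifiable

  expect_error(detect_communities(x, block_spin(c(8, 8), diag(2))),
               "critical")
})
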