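## Independent reference computations used for validation: brute-force
## enumeration over all 2^N configurations, exact pair correlations through
## the sufficient statistic, the de Finetti integral identity evaluated by
## quadrature, relative entropy with the Sanov-type tail bound, and batch
## recovery experiments.

#' Exact pair correlations by brute-force enumeration
#'
#' Sums \eqn{x_i x_j e^{-H(x)}} over all \eqn{2^N} configurations. The
#' slowest but most transparent route to \eqn{E(X_i X_j)}; guarded at
#' `N <= 16`.
#'
#' @param model A `"block_spin"` model with `N <= 16`.
#' @return An `N x N` symmetric matrix of exact pair expectations (unit
#'   diagonal).
#' @examples
#' enumerate_pair_correlations(block_spin(2, matrix(1)))[1, 2]  # tanh(0.5)
#' @seealso [sufficient_pair_correlations()] for the scalable exact route.
#' @export
enumerate_pair_correlations <- function(model) {
  stopifnot(inherits(model, "block_spin"))
  N <- model$N
  if (N > 16) stop("brute-force enumeration is guarded at N <= 16")
  X <- as.matrix(expand.grid(rep(list(c(-1, 1)), N), KEEP.OUT.ATTRS = FALSE))
  dimnames(X) <- NULL
  S <- .group_sums(model, X)
  A <- .pair_coupling(model)
  lw <- 0.5 * rowSums((S %*% A) * S)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  C <- crossprod(X, X * w)
  (C + t(C)) / 2
}

#' Exact pair correlations through the sufficient statistic
#'
#' Conditionally on the group-sum vector `s` the configuration is uniform
#' over placements, so for two distinct individuals
#' \deqn{E(X_i X_j \mid s) = \frac{s_l^2 - N_l}{N_l (N_l - 1)} \;(i,j \in l),
#'   \qquad E(X_i X_j \mid s) = \frac{s_l s_m}{N_l N_m} \;(i \in l, j \in m).}
#' Averaging over the enumerated [group_sum_distribution()] yields exact
#' expectations at cost \eqn{\prod_l (N_l+1)} instead of \eqn{2^N}, reaching
#' populations in the thousands when `M` is small.
#'
#' @param model A `"block_spin"` model.
#' @param cap State-space cap (see [group_sum_distribution()]).
#' @param by_group If `TRUE`, return the `M x M` matrix of per-group-pair
#'   expectations instead of the full `N x N` matrix.
#' @return Symmetric matrix of exact pair expectations.
#' @export
sufficient_pair_correlations <- function(model, cap = 5e6, by_group = FALSE) {
  stopifnot(inherits(model, "block_spin"))
  d <- group_sum_distribution(model, cap = cap)
  w <- exp(d$log_prob)
  S <- d$support
  M <- model$M
  EC <- matrix(0, M, M)
  for (l in seq_len(M)) {
    Nl <- model$sizes[l]
    EC[l, l] <- sum(w * (S[, l]^2 - Nl)) / (Nl * (Nl - 1))
    if (l < M) {
      for (m in seq(l + 1, M)) {
        EC[l, m] <- EC[m, l] <-
          sum(w * S[, l] * S[, m]) / (model$sizes[l] * model$sizes[m])
      }
    }
  }
  if (by_group) return(EC)
  C <- EC[model$labels, model$labels]
  diag(C) <- 1
  C
}

#' Pair correlation via the de Finetti integral identity
#'
#' Evaluates \eqn{E(X_i X_j) = Z_2(N)/Z_0(N)} with
#' \deqn{Z_2 = \int e^{-N F(x)} \tanh(x_{\iota(i)}/\sqrt{\alpha_{\iota(i)}})
#'   \tanh(x_{\iota(j)}/\sqrt{\alpha_{\iota(j)}})\, dx, \qquad
#'   Z_0 = \int e^{-N F(x)}\, dx,}
#' by quadrature (guarded at `M <= 2`): adaptive `stats::integrate` for
#' `M = 1`, tensor-product Gauss-Legendre with order doubling for `M = 2`.
#' The domain is truncated to the box where \eqn{N(F - \min F) \le 40} (the
#' integrand is below \eqn{e^{-40}} relative to its peak outside), which
#' covers every minimum of `F` in both regimes. This is an independent cross-check of the
#' enumeration and sufficient-statistic routes — three different
#' representations of the same expectation.
#'
#' @param model A `"block_spin"` model with `M <= 2`.
#' @param i,j Distinct individual indices.
#' @param log_cutoff Truncation threshold for \eqn{N(F - \min F)}
#'   (default 40).
#' @return The pair expectation, accurate to about `1e-8` for moderate `N`.
#' @export
definetti_pair_correlation <- function(model, i, j, log_cutoff = 40) {
  stopifnot(inherits(model, "block_spin"))
  if (model$M > 2) stop("quadrature is guarded at M <= 2")
  if (i == j) stop("'i' and 'j' must be distinct")
  N <- model$N
  sa <- sqrt(model$alpha)
  li <- model$labels[i]; lj <- model$labels[j]
  L <- find_minima(model, compute_z = FALSE)
  fmin <- L$fval
  ## box half-width: outside |x_k| > R every point has N(F - fmin) > cutoff;
  ## F grows at least quadratically, scan outward from the outermost minimum
  R <- max(abs(L$minima)) + 1
  while (any(N * (free_energy(model, .box_faces(R, model$M)) - fmin) <
             log_cutoff)) {
    R <- R * 1.5
    if (R > 1e3) break
  }
  if (model$M == 1) {
    f0 <- function(x) exp(-N * (free_energy(model, matrix(x)) - fmin))
    f2 <- function(x) f0(x) * tanh(x / sa[1])^2   # li == lj when M = 1
    Z0 <- stats::integrate(Vectorize(f0), -R, R, rel.tol = 1e-10,
                           abs.tol = 0, subdivisions = 500L)$value
    Z2 <- stats::integrate(Vectorize(f2), -R, R, rel.tol = 1e-10,
                           abs.tol = 0, subdivisions = 500L)$value
    return(Z2 / Z0)
  }
  ## tensor-product Gauss-Legendre, order doubled until the ratio stabilises
  ## (the integrand is analytic, so convergence is geometric)
  ratio_at <- function(nodes) {
    q <- pracma::gaussLegendre(nodes, -R, R)
    G <- as.matrix(expand.grid(q$x, q$x))
    W <- as.vector(outer(q$w, q$w))
    e <- exp(-N * (free_energy(model, G) - fmin))
    ti <- tanh(G[, li] / sa[li])
    tj <- tanh(G[, lj] / sa[lj])
    sum(W * e * ti * tj) / sum(W * e)
  }
  prev <- ratio_at(64L)
  for (nodes in c(128L, 256L, 512L)) {
    cur <- ratio_at(nodes)
    if (abs(cur - prev) < 1e-9 * max(1, abs(cur))) return(cur)
    prev <- cur
  }
  warning("quadrature did not stabilise to 1e-9; returning the finest value")
  prev
}

## sample points on the faces of the box [-R, R]^M (corners + face centres)
.box_faces <- function(R, M) {
  pts <- as.matrix(expand.grid(rep(list(c(-R, 0, R)), M)))
  pts[rowSums(abs(pts) == R) > 0, , drop = FALSE]
}

#' Relative entropy of two two-point laws
#'
#' \eqn{H(\nu \mid \theta) = \sum_r \nu(r) \log(\nu(r)/\theta(r))} for laws
#' on \eqn{\{-1, +1\}} (the distribution of a spin product). Conventions:
#' \eqn{0 \log 0 = 0}; the value is \eqn{+\infty} when \eqn{\nu} charges a
#' point of \eqn{\theta}-probability zero. Satisfies the quadratic lower
#' bound \eqn{H(\nu|\theta) \ge \varepsilon^2/8} whenever the means differ
#' by at least \eqn{\varepsilon} — the inequality behind all the package's
#' failure bounds.
#'
#' @param nu,theta Two-point laws: either the probability of \eqn{-1}
#'   (scalar in \eqn{[0,1]}) or a vector `c(p_minus, p_plus)`.
#' @return Nonnegative scalar, possibly `Inf`.
#' @examples
#' relative_entropy(0.5, 0.25)   # 0.5 log 2 + 0.5 log(2/3)
#' @export
relative_entropy <- function(nu, theta) {
  p <- .as_pair_law(nu)
  q <- .as_pair_law(theta)
  terms <- numeric(2)
  for (r in 1:2) {
    if (p[r] == 0) next
    if (q[r] == 0) return(Inf)
    terms[r] <- p[r] * log(p[r] / q[r])
  }
  sum(terms)
}

.as_pair_law <- function(x) {
  x <- as.numeric(x)
  p <- if (length(x) == 1L) c(x, 1 - x) else x
  if (length(p) != 2L || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop("a two-point law is a probability of -1, or c(p_minus, p_plus)")
  }
  p
}

#' Sanov-type tail bound for empirical pair correlations
#'
#' Upper bound \eqn{(n+1)^2 e^{-n\varepsilon^2/8}} on the probability that
#' the empirical mean of `n` i.i.d. \eqn{\pm 1} products deviates from its
#' expectation by at least `eps`. Finite-`n` (no limits involved), hence
#' usable to size samples exactly.
#'
#' @param n Sample size (vectorised).
#' @param eps Deviation threshold in (0, 1).
#' @return Numeric vector of bounds.
#' @examples
#' sanov_upper_bound(100, 0.3)
#' @export
sanov_upper_bound <- function(n, eps) {
  if (any(eps <= 0) || any(eps >= 1)) stop("'eps' must be in (0, 1)")
  (n + 1)^2 * exp(-n * eps^2 / 8)
}

#' Batch recovery experiment
#'
#' Repeatedly simulates a sample from the model, runs the regime-appropriate
#' window detection, and compares the recovered partition with the planted
#' one as unlabelled partitions (the theory promises the partition, not the
#' group names). Fully seeded: replicate `r` uses seed `seed + r - 1` for
#' its sample, so summaries are reproducible and individual failures can be
#' replayed.
#'
#' For observation counts beyond `chunk` the empirical correlations are
#' accumulated chunk-wise so memory stays bounded.
#'
#' @param model A `"block_spin"` model in a non-critical regime.
#' @param n Observations per replicate.
#' @param reps Number of replicates (0 gives an empty summary).
#' @param seed Base seed.
#' @param spec Optional `"level_spec"` override (defaults to the model's
#'   regime theory).
#' @param chunk Observations per sampling chunk (default `1e5`).
#' @return An object of class `"recovery_summary"`: list with `reps`,
#'   `successes`, `rate`, `statuses` and `exact_match` (logical per
#'   replicate).
#' @export
recovery_experiment <- function(model, n, reps, seed = 1, spec = NULL,
                                chunk = 1e5) {
  stopifnot(inherits(model, "block_spin"))
  reg <- spin_regime(model)$regime
  if (reg == "critical") stop("recovery is undefined in the critical regime")
  if (is.null(spec)) {
    spec <- if (reg == "high") {
      level_spec(pair_limit_high(model))
    } else {
      level_spec(z_vectors(model, find_minima(model, compute_z = FALSE)))
    }
  }
  reps <- as.integer(reps)
  if (reps < 0) stop("'reps' must be nonnegative")
  statuses <- character(reps)
  match_ok <- logical(reps)
  d <- if (reps > 0) group_sum_distribution(model) else NULL
  p <- if (reps > 0) exp(d$log_prob) else NULL
  for (r in seq_len(reps)) {
    CP <- matrix(0, model$N, model$N)
    done <- 0
    .with_seed(seed + r - 1, {
      while (done < n) {
        m_draw <- min(chunk, n - done)
        idx <- sample.int(nrow(d$support), m_draw, replace = TRUE, prob = p)
        X <- .place_spins(model, d$support[idx, , drop = FALSE])
        CP <- CP + crossprod(X)
        done <- done + m_draw
      }
    })
    corr <- CP / n
    res <- identify_groups(corr, spec)
    statuses[r] <- res$status
    match_ok[r] <- res$status == "success" &&
      .same_partition(res$membership, model$labels)
  }
  structure(
    list(reps = reps, successes = sum(match_ok),
         rate = if (reps > 0) mean(match_ok) else NA_real_,
         statuses = statuses, exact_match = match_ok,
         n = n, seed = seed),
    class = "recovery_summary"
  )
}

## unlabelled partition equality: same co-membership structure, no NAs
.same_partition <- function(a, b) {
  if (anyNA(a) || length(a) != length(b)) return(FALSE)
  ca <- match(a, unique(a))
  cb <- match(b, unique(b))
  all(ca == cb)
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf(
    "Recovery experiment: %d/%d exact recoveries (rate %s) at n = %s\n",
    x$successes, x$reps,
    ifelse(is.na(x$rate), "NA", format(x$rate)), format(x$n)))
  if (x$reps > 0 && any(x$statuses != "success")) {
    print(table(x$statuses))
  }
  invisible(x)
}
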