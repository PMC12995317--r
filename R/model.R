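#' Construct a block spin Ising model
#'
#' A block spin Ising model describes `N` dependent \eqn{\pm 1}-valued
#' variables ("spins" or "votes"), one per individual, partitioned into `M`
#' latent groups. Individuals interact through a symmetric positive-definite
#' coupling matrix `J`, whose entry \eqn{J_{lm}} couples every pair with one
#' member in group `l` and the other in group `m`. The energy of a
#' configuration \eqn{x \in \{-1,1\}^N} is
#' \deqn{H(x) = -\tfrac12 \sum_{l,m} \frac{J_{lm}}{\sqrt{N_l N_m}} s_l s_m,
#'   \quad s_l = \sum_{i : \iota(i)=l} x_i,}
#' (the double sum over individuals includes the \eqn{i=j} diagonal terms,
#' which this group-sum factorisation preserves), and configurations are
#' observed with probability \eqn{Z^{-1} e^{-H(x)}}. For `M = 1` this is the
#' classical Curie-Weiss model with inverse temperature `J[1,1]`.
#'
#' `J` must be symmetric up to `1e-12 * max(abs(J))` (it is then symmetrised by
#' averaging) and positive definite: its smallest eigenvalue must exceed
#' `1e-10` times its largest absolute eigenvalue. Every group must have at
#' least two members.
#'
#' @param sizes Integer vector of group sizes \eqn{N_1, \dots, N_M}, all
#'   at least 2.
#' @param J Coupling matrix, `M x M`, symmetric positive definite
#'   (dimensionless; subsumes the inverse temperature).
#' @param labels Optional length-`N` integer vector assigning each individual
#'   to a group in `1..M`. Defaults to contiguous blocks: the first
#'   `sizes[1]` individuals form group 1, and so on.
#' @return An object of class `"block_spin"`: a list with elements `sizes`,
#'   `J`, `labels`, `N`, `M` and `alpha` (the group-size fractions
#'   \eqn{\alpha_l = N_l/N}).
#' @examples
#' m <- block_spin(c(3, 3), matrix(c(0.6, 0.1, 0.1, 0.5), 2, 2))
#' m
#' hamiltonian(m, rep(1, 6))
#' @seealso [spin_regime()], [simulate.block_spin()], [three_party_model()]
#' @export
block_spin <- function(sizes, J, labels = NULL) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || anyNA(sizes)) {
    stop("'sizes' must be a nonempty integer vector")
  }
  if (any(sizes < 2L)) {
    stop("every group must contain at least two individuals")
  }
  M <- length(sizes)
  N <- sum(sizes)
  J <- as.matrix(J)
  if (!is.numeric(J) || nrow(J) != M || ncol(J) != M) {
    stop("'J' must be a numeric ", M, " x ", M, " matrix matching length(sizes)")
  }
  scale <- max(abs(J))
  if (scale == 0 || max(abs(J - t(J))) > 1e-12 * scale) {
    stop("'J' must be symmetric (tolerance 1e-12 relative to max|J|)")
  }
  J <- (J + t(J)) / 2
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) {
    stop("'J' must be positive definite")
  }
  if (is.null(labels)) {
    labels <- rep.int(seq_len(M), sizes)
  } else {
    labels <- as.integer(labels)
    if (length(labels) != N || anyNA(labels) ||
        any(labels < 1L) || any(labels > M)) {
      stop("'labels' must be a length-", N, " vector with entries in 1..", M)
    }
    if (!identical(tabulate(labels, nbins = M), sizes)) {
      stop("'labels' group counts are inconsistent with 'sizes'")
    }
  }
  structure(
    list(sizes = sizes, J = J, labels = labels,
         N = N, M = M, alpha = sizes / N),
    class = "block_spin"
  )
}

#' @export
print.block_spin <- function(x, ...) {
  cat("Block spin Ising model\n")
  cat("  individuals N =", x$N, " groups M =", x$M,
      " sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  coupling matrix J:\n")
  print(x$J)
  reg <- spin_regime(x)
  cat("  regime:", reg$regime,
      sprintf("(min eig(I - J) = %.6g)", min(reg$eigenvalues)), "\n")
  invisible(x)
}

#' @export
summary.block_spin <- function(object, ...) {
  reg <- spin_regime(object)
  out <- list(model = object, regime = reg)
  if (reg$regime == "high") {
    out$theory <- pair_limit_high(object)
  }
  class(out) <- "summary.block_spin"
  out
}

#' @export
print.summary.block_spin <- function(x, ...) {
  print(x$model)
  cat("\nSpectrum of I - J (ascending):",
      paste(signif(x$regime$eigenvalues, 6), collapse = ", "), "\n")
  if (!is.null(x$theory)) {
    cat("High-temperature limit matrix (N * limiting pair correlations):\n")
    print(x$theory$limit_matrix)
  }
  invisible(x)
}

#' Classify the temperature regime of a coupling matrix
#'
#' The behaviour of the model is governed by the spectrum of \eqn{I - J}:
#' the model is in the high temperature regime when \eqn{I - J} is positive
#' definite (weak dependence; pair correlations of order 1/N), in the low
#' temperature regime when \eqn{I - J} has a negative eigenvalue (strong
#' dependence; pair correlations of order 1), and critical on the boundary.
#' Community detection is supported in the two non-critical regimes only.
#'
#' @param x A `"block_spin"` model or a symmetric positive-definite coupling
#'   matrix.
#' @param tol Spectral tolerance for calling an eigenvalue zero. Defaults to
#'   `1e-10` times the largest absolute eigenvalue of \eqn{I - J}.
#' @return An object of class `"spin_regime"`: list with `regime` (one of
#'   `"high"`, `"critical"`, `"low"`), `eigenvalues` (of \eqn{I - J}, sorted
#'   ascending) and `tol`.
#' @examples
#' spin_regime(matrix(0.5))                    # high
#' spin_regime(matrix(2))                      # low
#' spin_regime(three_party_model())$regime     # "high"
#' @export
spin_regime <- function(x, tol = NULL) {
  J <- if (inherits(x, "block_spin")) x$J else as.matrix(x)
  if (max(abs(J - t(J))) > 1e-12 * max(abs(J))) {
    stop("coupling matrix must be symmetric")
  }
  ev <- sort(eigen(diag(nrow(J)) - J, symmetric = TRUE, only.values = TRUE)$values)
  if (is.null(tol)) tol <- 1e-10 * max(abs(ev), 1e-300)
  regime <- if (min(ev) > tol) "high" else if (min(ev) < -tol) "low" else "critical"
  structure(list(regime = regime, eigenvalues = ev, tol = tol),
            class = "spin_regime")
}

#' @export
print.spin_regime <- function(x, ...) {
  cat("Regime:", x$regime, "\n")
  cat("Eigenvalues of I - J:", paste(signif(x$eigenvalues, 6), collapse = ", "), "\n")
  invisible(x)
}

## J_lm / sqrt(N_l N_m), the per-pair coupling used by the group-sum forms
.pair_coupling <- function(model) {
  model$J / sqrt(outer(model$sizes, model$sizes))
}

.check_config <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) == 1L && nrow(x) == model$N) x <- t(x)
  if (ncol(x) != model$N) {
    stop("configuration length must equal N = ", model$N)
  }
  if (!all(x == 1 | x == -1)) {
    stop("configuration entries must be -1 or +1")
  }
  x
}

## rows of x -> M-column matrix of group sums
.group_sums <- function(model, x) {
  G <- matrix(0, model$N, model$M)
  G[cbind(seq_len(model$N), model$labels)] <- 1
  x %*% G
}

#' Hamiltonian of spin configurations
#'
#' Evaluates the configuration energy through the group sums
#' \eqn{s_l = \sum_{i:\iota(i)=l} x_i}:
#' \eqn{H(x) = -\tfrac12 \sum_{l,m} J_{lm} s_l s_m / \sqrt{N_l N_m}}.
#' Lower energy means higher probability; the energy is even under the global
#' spin flip \eqn{x \to -x}.
#'
#' @param model A `"block_spin"` model.
#' @param x A configuration vector of length `N` with entries in
#'   \eqn{\{-1, 1\}}, or a matrix with one configuration per row.
#' @return Numeric vector of energies, one per configuration.
#' @examples
#' m <- block_spin(2, matrix(1))
#' hamiltonian(m, c(1, -1))   # 0
#' hamiltonian(m, c(1, 1))    # -1
#' @export
hamiltonian <- function(model, x) {
  stopifnot(inherits(model, "block_spin"))
  x <- .check_config(model, x)
  S <- .group_sums(model, x)
  A <- .pair_coupling(model)
  -0.5 * rowSums((S %*% A) * S)
}

## log of the partition-function via the sufficient statistic:
## Z = sum_s prod_l C(N_l, (N_l+s_l)/2) * exp(-H(s))
.log_partition <- function(model, cap = 5e6) {
  d <- group_sum_distribution(model, cap = cap)
  d$log_Z
}

#' Exact log-probability of a configuration
#'
#' Computes \eqn{\log P(X = x) = -H(x) - \log Z}. The normalisation
#' constant is obtained exactly by summing the Gibbs weights over the
#' group-sum sufficient statistic (a state space of size
#' \eqn{\prod_l (N_l + 1)}) rather than over all \eqn{2^N} configurations,
#' so moderately large populations remain tractable when `M` is small.
#'
#' @inheritParams hamiltonian
#' @param cap Maximum admissible sufficient-statistic state-space size.
#' @return Numeric vector of log-probabilities, one per configuration row.
#'   Exponentials over all \eqn{2^N} configurations sum to one.
#' @examples
#' m <- block_spin(2, matrix(1))
#' log_probability(m, c(1, 1))   # log(e / (2 e + 2))
#' @export
log_probability <- function(model, x, cap = 5e6) {
  stopifnot(inherits(model, "block_spin"))
  -hamiltonian(model, x) - .log_partition(model, cap = cap)
}
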