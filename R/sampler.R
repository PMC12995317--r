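## Exact sampling through the group-sum sufficient statistic.
##
## The Gibbs measure depends on a configuration only through the vector of
## group sums s = (s_1, ..., s_M), s_l in {-N_l, -N_l+2, ..., N_l}. The
## pushforward of the measure under s has weights
##   P(s) ∝ prod_l C(N_l, (N_l+s_l)/2) * exp( (1/2) sum_{lm} J_lm s_l s_m /
##          sqrt(N_l N_m) ),
## and conditionally on s the configuration is uniform over placements:
## each group independently chooses which (N_l+s_l)/2 members are +1.

## run code with a locally seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

#' Exact distribution of the group-sum vector
#'
#' Enumerates the pushforward of the model's probability measure under the
#' sufficient statistic \eqn{s_l = \sum_{i:\iota(i)=l} x_i}. The support has
#' \eqn{\prod_l (N_l + 1)} points; weights combine the binomial multiplicity
#' of each sum (computed in log space via `lchoose`) with the Gibbs factor,
#' and are normalised by log-sum-exp so no underflow occurs.
#'
#' @param model A `"block_spin"` model.
#' @param cap Maximum admissible support size; beyond it the enumeration is
#'   refused (use [gibbs_draw_sample()] instead).
#' @return An object of class `"sum_distribution"`: list with `support`
#'   (matrix, one group-sum vector per row), `log_prob` (aligned normalised
#'   log-probabilities), `log_Z` (log partition function) and `model`.
#' @examples
#' d <- group_sum_distribution(block_spin(2, matrix(1)))
#' cbind(d$support, p = exp(d$log_prob))   # P(s = +-2) = e/(2e+2)
#' @export
group_sum_distribution <- function(model, cap = 5e6) {
  stopifnot(inherits(model, "block_spin"))
  size <- prod(model$sizes + 1)
  if (size > cap) {
    stop("sufficient-statistic state space (", format(size, big.mark = ","),
         ") exceeds cap; use gibbs_draw_sample()")
  }
  grids <- lapply(model$sizes, function(Nl) seq.int(-Nl, Nl, by = 2L))
  S <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(S) <- NULL
  logmult <- rowSums(vapply(
    seq_len(model$M),
    function(l) lchoose(model$sizes[l], (model$sizes[l] + S[, l]) / 2),
    numeric(nrow(S))
  ))
  A <- .pair_coupling(model)
  lw <- logmult + 0.5 * rowSums((S %*% A) * S)
  mx <- max(lw)
  log_Z <- mx + log(sum(exp(lw - mx)))
  structure(
    list(support = S, log_prob = lw - log_Z, log_Z = log_Z, model = model),
    class = "sum_distribution"
  )
}

#' @export
print.sum_distribution <- function(x, ...) {
  cat("Group-sum distribution:", nrow(x$support), "support points,",
      "log Z =", format(x$log_Z), "\n")
  invisible(x)
}

## Given a matrix of drawn group-sum vectors (one per row), place spins:
## group l gets (N_l + s_l)/2 uniformly chosen +1 entries. Vectorised via
## row-wise uniform ranks.
.place_spins <- function(model, Smat) {
  n <- nrow(Smat)
  X <- matrix(-1, n, model$N)
  for (l in seq_len(model$M)) {
    cols <- which(model$labels == l)
    Nl <- model$sizes[l]
    kplus <- (Nl + Smat[, l]) / 2
    U <- matrix(stats::runif(n * Nl), n, Nl)
    o <- order(rep(seq_len(n), times = Nl), as.vector(U))
    rk <- integer(n * Nl)
    rk[o] <- rep(seq_len(Nl), times = n)
    up <- matrix(rk, n, Nl) <= kplus   # kplus recycles down columns = per row
    X[, cols][up] <- 1
  }
  X
}

#' Draw exact i.i.d. samples from a block spin model
#'
#' Each observation is drawn exactly in two stages: a group-sum vector from
#' the enumerated sufficient-statistic distribution, then a uniformly random
#' placement of the \eqn{(N_l + s_l)/2} positive spins within each group.
#' Both stages consume one explicitly seeded RNG stream, in that order, so
#' results are reproducible bit-for-bit given `seed`.
#'
#' @param model A `"block_spin"` model.
#' @param n Number of observations (rows) to draw.
#' @param seed Integer seed for the sample's private RNG stream; the caller's
#'   RNG state is left untouched. `NULL` continues the current stream.
#' @param cap Sufficient-statistic state-space cap, as in
#'   [group_sum_distribution()].
#' @return An `n x N` matrix of \eqn{\pm 1} entries of class `"spin_sample"`,
#'   with attributes `seed`, `method` (`"exact"`) and `model_digest`.
#' @examples
#' m <- block_spin(c(2, 2), 0.5 * diag(2))
#' x <- draw_sample(m, 5, seed = 1)
#' x
#' @seealso [gibbs_draw_sample()] for large state spaces,
#'   [simulate.block_spin()] for the generic interface.
#' @export
draw_sample <- function(model, n, seed = NULL, cap = 5e6) {
  stopifnot(inherits(model, "block_spin"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  d <- group_sum_distribution(model, cap = cap)
  p <- exp(d$log_prob)
  X <- .with_seed(seed, {
    idx <- sample.int(nrow(d$support), n, replace = TRUE, prob = p)
    .place_spins(model, d$support[idx, , drop = FALSE])
  })
  .spin_sample(X, model, method = "exact", seed = seed)
}

.spin_sample <- function(X, model, method, seed, extra = NULL) {
  attr(X, "seed") <- seed
  attr(X, "method") <- method
  attr(X, "model_digest") <- .model_digest(model)
  for (nm in names(extra)) attr(X, nm) <- extra[[nm]]
  class(X) <- c("spin_sample", class(X))
  X
}

.model_digest <- function(model) {
  paste0("sizes=", paste(model$sizes, collapse = ","),
         ";J=", paste(format(model$J, digits = 17), collapse = ","))
}

#' @export
print.spin_sample <- function(x, ...) {
  cat("Spin sample:", nrow(x), "observations of", ncol(x), "individuals",
      sprintf("(method = %s, seed = %s)\n",
              attr(x, "method"), format(attr(x, "seed"))))
  if (nrow(x) <= 10 && ncol(x) <= 20) print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Simulate observations from a block spin model
#'
#' Method for the [stats::simulate()] generic; draws `nsim` exact
#' observations via [draw_sample()].
#'
#' @param object A `"block_spin"` model.
#' @param nsim Number of observations.
#' @param seed Integer seed (see [draw_sample()]).
#' @param ... Passed to [draw_sample()].
#' @return A `"spin_sample"` matrix.
#' @export
simulate.block_spin <- function(object, nsim = 1, seed = NULL, ...) {
  draw_sample(object, n = nsim, seed = seed, ...)
}

#' Approximate sampling by Gibbs (heat-bath) sweeps
#'
#' Fallback sampler for models whose sufficient-statistic state space exceeds
#' the enumeration cap. Single-site heat-bath updates: spin `i` in group `l`
#' is redrawn from its conditional distribution,
#' \eqn{P(x_i = +1 \mid x_{-i}) = 1/(1 + e^{-2 f_i})} with local field
#' \eqn{f_i = \sum_m A_{lm} s_m - A_{ll} x_i}, \eqn{A_{lm} = J_{lm}/\sqrt{N_l
#' N_m}}. One sweep updates all `N` sites in order. Rows are taken `thin`
#' sweeps apart after `burn_in` sweeps. Output is approximate (Markov chain),
#' unlike [draw_sample()]; the method is recorded in the sample's metadata.
#'
#' @param model A `"block_spin"` model.
#' @param n Number of observations to record.
#' @param seed Integer seed for the chain's private RNG stream.
#' @param burn_in Number of initial sweeps discarded (default `100`).
#' @param thin Number of sweeps between recorded rows (default `10`).
#' @return A `"spin_sample"` matrix with `method = "gibbs"` and the chain
#'   parameters in its attributes.
#' @examples
#' m <- block_spin(c(5, 5), matrix(c(0.6, 0.1, 0.1, 0.5), 2, 2))
#' x <- gibbs_draw_sample(m, 3, seed = 1)
#' attr(x, "method")
#' @export
gibbs_draw_sample <- function(model, n, seed = NULL, burn_in = 100, thin = 10) {
  stopifnot(inherits(model, "block_spin"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (burn_in < 1L || thin < 1L) stop("'burn_in' and 'thin' must be >= 1")
  A <- .pair_coupling(model)
  lab <- model$labels
  N <- model$N
  X <- matrix(-1, n, N)
  .with_seed(seed, {
    x <- sample(c(-1, 1), N, replace = TRUE)
    s <- vapply(seq_len(model$M), function(l) sum(x[lab == l]), numeric(1))
    sweep1 <- function() {
      for (i in seq_len(N)) {
        l <- lab[i]
        f <- sum(A[l, ] * s) - A[l, l] * x[i]
        xi_new <- if (stats::runif(1) < 1 / (1 + exp(-2 * f))) 1 else -1
        if (xi_new != x[i]) {
          s[l] <<- s[l] + (xi_new - x[i])
          x[i] <<- xi_new
        }
      }
    }
    for (b in seq_len(burn_in)) sweep1()
    for (t in seq_len(n)) {
      for (k in seq_len(thin)) sweep1()
      X[t, ] <- x
    }
  })
  .spin_sample(X, model, method = "gibbs", seed = seed,
               extra = list(burn_in = burn_in, thin = thin))
}
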