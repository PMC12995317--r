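## Mean-field free-energy landscape.
##
## The de Finetti representation writes model expectations as ratios of
## integrals of exp(-N F) over R^M, with
##   F(x) = (1/2) x' J^{-1} x - sum_l alpha_l log cosh(x_l / sqrt(alpha_l)).
## The sqrt(alpha) scaling inside cosh (and inside the tanh factors of the
## numerator integrals) is forced by the Hubbard-Stratonovich derivation:
## summing exp(u's(x)) over configurations with s_l(x) = group sum / sqrt(alpha_l)
## produces prod_l cosh^{N_l}(u_l/sqrt(alpha_l)), and it is the unique
## convention under which the Hessian of F at 0 equals H = J^{-1} - I.
##
## Laplace approximation around the minima of F then gives the limiting pair
## correlations. High temperature (unique minimum at 0):
##   E(X_i X_j) -> H^{-1}_{lm} / sqrt(N_l N_m),   l = iota(i), m = iota(j).
## Equivalently K_{lm}/N with the size-adjusted limit matrix
##   K = D^{-1/2} H^{-1} D^{-1/2},  D = diag(alpha),
## which is the inverse of the s.p.d. matrix D^{1/2} H D^{1/2}, so the
## strict off-diagonal bound off < max(diagonals) still holds for K.
## Low temperature (minima z^(1..K), Hessians H_k):
##   E(X_i X_j) -> <Z_l, Z_m>, the Gram matrix of the per-group vectors
##   Z_l[k] = det(H_k)^{-1/4} tanh(z_l^(k)/sqrt(alpha_l)) /
##            sqrt(sum_k det(H_k)^{-1/2}).

#' Mean-field free energy of a block spin model
#'
#' Evaluates
#' \deqn{F(x) = \tfrac12 x^T J^{-1} x - \sum_l \alpha_l \ln\cosh(x_l/\sqrt{\alpha_l})}
#' on \eqn{R^M}. `F` is even, `F(0) = 0`, and its minima control the model's
#' large-`N` behaviour through the Laplace approximation of the de Finetti
#' integrals: a unique minimum at the origin in the high temperature regime,
#' and `K >= 2` sign-symmetric minima in the (non-critical) low temperature
#' regime.
#'
#' @param model A `"block_spin"` model.
#' @param x Point in \eqn{R^M}, or a matrix with one point per row.
#' @return Numeric vector of free-energy values.
#' @examples
#' m <- block_spin(c(4, 4), matrix(c(1.5, -0.1, -0.1, 1.5), 2, 2))
#' free_energy(m, c(0, 0))   # 0
#' @seealso [free_energy_derivatives()], [find_minima()]
#' @export
free_energy <- function(model, x) {
  stopifnot(inherits(model, "block_spin"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != model$M) stop("'x' must have M = ", model$M, " columns")
  Jinv <- solve(model$J)
  sa <- sqrt(model$alpha)
  q <- 0.5 * rowSums((x %*% Jinv) * x)
  ## log cosh computed stably for large arguments
  lc <- function(t) abs(t) + log1p(exp(-2 * abs(t))) - log(2)
  q - as.vector(lc(sweep(x, 2, sa, "/")) %*% model$alpha)
}

#' Gradient and Hessian of the free energy
#'
#' Closed forms: gradient component
#' \eqn{(J^{-1}x)_l - \sqrt{\alpha_l}\tanh(x_l/\sqrt{\alpha_l})}, Hessian
#' \eqn{J^{-1} - I + \mathrm{diag}(\tanh^2(x_l/\sqrt{\alpha_l}))}. At the
#' origin the Hessian equals \eqn{H = J^{-1} - I} exactly, the matrix whose
#' inverse drives the high-temperature correlation limits.
#'
#' @inheritParams free_energy
#' @param x Point in \eqn{R^M}.
#' @return List with elements `gradient` (length `M`) and `hessian`
#'   (`M x M`, symmetric).
#' @export
free_energy_derivatives <- function(model, x) {
  stopifnot(inherits(model, "block_spin"))
  x <- as.numeric(x)
  if (length(x) != model$M) stop("'x' must have length M = ", model$M)
  Jinv <- solve(model$J)
  sa <- sqrt(model$alpha)
  th <- tanh(x / sa)
  list(
    gradient = as.vector(Jinv %*% x) - sa * th,
    hessian = Jinv - diag(model$M) + diag(th^2, nrow = model$M)
  )
}

#' High-temperature pair-correlation theory
#'
#' In the high temperature regime (`I - J` positive definite) set
#' \eqn{H = J^{-1} - I}. The pair correlation of two individuals in groups
#' `l` and `m` converges to \eqn{H^{-1}_{lm}/\sqrt{N_l N_m}} as the
#' population grows (at rate \eqn{(\ln N)^{(6+M)/2}/N^2}). The size-adjusted
#' limit matrix \eqn{K = D_\alpha^{-1/2} H^{-1} D_\alpha^{-1/2}} collects the
#' `N`-scaled limits: the limiting correlation is `K[l, m] / N`. `K` is the
#' inverse of the symmetric positive-definite matrix
#' \eqn{D_\alpha^{1/2} H D_\alpha^{1/2}}, so every off-diagonal entry is
#' strictly below the larger of the two corresponding diagonals — the
#' property that makes level-window community detection work.
#'
#' @param model A `"block_spin"` model in the high temperature regime.
#' @return An object of class `"high_temp_theory"`: list with `H`, `Hinv`,
#'   `alpha`, `N`, `limit_matrix` (`K` above) and `pair_limit`
#'   (`K/N`, the matrix of limiting correlations by group pair).
#' @examples
#' th <- pair_limit_high(three_party_model())
#' round(th$Hinv, 4)   # diagonal 5.5517, 2.7931, 1.7586
#' @seealso [separation_constants()], [level_spec()]
#' @export
pair_limit_high <- function(model) {
  stopifnot(inherits(model, "block_spin"))
  reg <- spin_regime(model)
  if (reg$regime != "high") {
    stop("model is not in the high temperature regime (regime = ",
         reg$regime, ")")
  }
  H <- solve(model$J) - diag(model$M)
  Hinv <- solve(H)
  Hinv <- (Hinv + t(Hinv)) / 2
  K <- Hinv / sqrt(outer(model$alpha, model$alpha))
  structure(
    list(H = H, Hinv = Hinv, alpha = model$alpha, N = model$N,
         limit_matrix = K, pair_limit = K / model$N),
    class = "high_temp_theory"
  )
}

#' @export
print.high_temp_theory <- function(x, ...) {
  cat("High-temperature pair-correlation theory (H = J^-1 - I)\n")
  cat("H^-1:\n"); print(x$Hinv)
  cat("Size-adjusted limit matrix K (limiting correlation = K/N):\n")
  print(x$limit_matrix)
  invisible(x)
}

## box radius within which all minima lie: at a stationary point
## z = J (sqrt(alpha) * tanh(z/sqrt(alpha))), so ||z|| <= ||J||_2
.minima_box <- function(model) {
  norm(model$J, type = "2") + 1
}

#' Locate the minima of the free energy
#'
#' Multi-start minimisation of [free_energy()]: quasi-Newton (BFGS) with the
#' analytic gradient from every sign pattern in \eqn{\{-1,0,1\}^M} scaled by
#' \eqn{2\sqrt{\alpha}}, plus `n_random` uniform starts in the box
#' \eqn{[-R,R]^M} with \eqn{R = \|J\|_2 + 1} (all stationary points satisfy
#' \eqn{\|z\| \le \|J\|_2}). Each candidate is polished by Newton steps with
#' the analytic Hessian, deduplicated at radius `1e-5` in the max norm,
#' restricted to global minima (value within `f_tol` of the best), closed
#' under the sign flip \eqn{z \to -z}, and verified: gradient norm below
#' `grad_tol` and Hessian positive definite. A Hessian that is not positive
#' definite at a minimum signals a critical landscape and raises an error.
#'
#' In the high temperature regime the landscape is strictly convex and the
#' unique minimum is the origin; in the non-critical low temperature regime
#' there are finitely many minima, in sign-symmetric pairs.
#'
#' @param model A `"block_spin"` model.
#' @param n_random Number of random extra starts (default 50).
#' @param f_tol Function-value tolerance for "global" (default `1e-9`).
#' @param grad_tol Gradient-norm verification tolerance (default `1e-8`).
#' @param seed Seed for the random starts (default 1; the landscape is
#'   deterministic, the seed only fixes the start set).
#' @param compute_z If `TRUE` (default), fill the `Z` vectors and their Gram
#'   matrix via [z_vectors()].
#' @return An object of class `"fe_landscape"`: list with `minima` (matrix,
#'   one minimum per row), `fval` (common minimum value), `hessians` (list),
#'   `dets` (their determinants), `K` (number of minima), and — when
#'   `compute_z` — `Z` (`M x K` matrix of per-group vectors), `gram`
#'   (`M x M`), `identifiable` flag.
#' @examples
#' m <- block_spin(4, matrix(2))          # Curie-Weiss, beta = 2
#' L <- find_minima(m)
#' L$minima                               # +- beta m*, m* = tanh(2 m*)
#' L$gram                                 # m*^2
#' @export
find_minima <- function(model, n_random = 50, f_tol = 1e-9,
                        grad_tol = 1e-8, seed = 1, compute_z = TRUE) {
  stopifnot(inherits(model, "block_spin"))
  M <- model$M
  R <- .minima_box(model)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), M)))
  starts <- sweep(signs, 2, 2 * sqrt(model$alpha), "*")
  rand <- .with_seed(seed, matrix(stats::runif(n_random * M, -R, R), n_random, M))
  starts <- rbind(starts, rand)
  dimnames(starts) <- NULL

  fn <- function(x) free_energy(model, x)
  gr <- function(x) free_energy_derivatives(model, x)$gradient

  cand <- matrix(NA_real_, 0, M)
  fv <- numeric(0)
  for (i in seq_len(nrow(starts))) {
    o <- try(stats::optim(starts[i, ], fn, gr, method = "BFGS",
                          control = list(reltol = 1e-14, maxit = 500)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    z <- .newton_polish(model, o$par)
    cand <- rbind(cand, z)
    fv <- c(fv, fn(z))
  }
  if (!length(fv)) stop("optimizer failed to converge from every start")
  best <- min(fv)
  keep <- which(fv <= best + f_tol)
  pts <- cand[keep, , drop = FALSE]
  ## close under sign flip (F is even), then dedup at 1e-5 in the max norm
  pts <- rbind(pts, -pts)
  pts <- .dedup_rows(pts, 1e-5)
  dimnames(pts) <- NULL
  ## verify each point
  hess <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    d <- free_energy_derivatives(model, pts[k, ])
    if (sqrt(sum(d$gradient^2)) > grad_tol) {
      stop("candidate minimum failed the gradient check (optimizer ",
           "non-convergence)")
    }
    ev <- eigen(d$hessian, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8 * max(abs(ev))) {
      stop("critical landscape: Hessian at a minimum is not positive definite")
    }
    hess[[k]] <- d$hessian
  }
  out <- list(
    model = model,
    minima = pts,
    fval = best,
    hessians = hess,
    dets = vapply(hess, det, numeric(1)),
    K = nrow(pts)
  )
  class(out) <- "fe_landscape"
  if (compute_z) out <- z_vectors(model, out)
  out
}

.newton_polish <- function(model, z, iter = 40) {
  for (k in seq_len(iter)) {
    d <- free_energy_derivatives(model, z)
    step <- try(solve(d$hessian, d$gradient), silent = TRUE)
    if (inherits(step, "try-error")) break
    if (max(abs(step)) > 1) step <- step / max(abs(step))  # damp far from minimum
    z <- z - step
    if (sqrt(sum(d$gradient^2)) < 1e-14) break
  }
  z
}

.dedup_rows <- function(x, tol) {
  if (nrow(x) <= 1) return(x)
  keep <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(x) - 1)) {
    if (!keep[i]) next
    for (j in seq(i + 1, nrow(x))) {
      if (keep[j] && max(abs(x[i, ] - x[j, ])) <= tol) keep[j] <- FALSE
    }
  }
  x[keep, , drop = FALSE]
}

#' @export
print.fe_landscape <- function(x, ...) {
  cat("Free-energy landscape:", x$K, "global minimum/minima, F =",
      format(x$fval), "\n")
  print(x$minima)
  if (!is.null(x$gram)) {
    cat("Gram matrix of Z vectors (limiting pair correlations):\n")
    print(x$gram)
    if (!x$identifiable)
      cat("WARNING: Z vectors not pairwise distinct; groups not identifiable\n")
  }
  invisible(x)
}

#' Per-group Z vectors and their Gram matrix
#'
#' From the minima \eqn{z^{(k)}} of the free energy and their Hessians
#' \eqn{H_k}, builds for each group `l` the vector
#' \deqn{Z_l[k] = \frac{\det(H_k)^{-1/4} \tanh(z^{(k)}_l/\sqrt{\alpha_l})}
#'   {\sqrt{\sum_j \det(H_j)^{-1/2}}},}
#' whose Gram matrix \eqn{\langle Z_l, Z_m\rangle} is the low-temperature
#' limit of the pair correlation between groups `l` and `m`:
#' \deqn{\langle Z_l, Z_m \rangle = \frac{\sum_k \det(H_k)^{-1/2}
#'   \tanh(z^{(k)}_l/\sqrt{\alpha_l}) \tanh(z^{(k)}_m/\sqrt{\alpha_m})}
#'   {\sum_k \det(H_k)^{-1/2}},}
#' the leading term of the Laplace approximation of the de Finetti integral
#' ratio. The normalisation is the unique one for which this holds.
#'
#' Detection in the low temperature regime requires the `Z` vectors to be
#' pairwise distinct; `identifiable` is `FALSE` when two groups share one
#' (within `1e-8`), in which case the limiting correlations cannot separate
#' them and low-temperature detection refuses to build a level specification.
#'
#' @param model A `"block_spin"` model.
#' @param landscape An `"fe_landscape"` from [find_minima()].
#' @return The landscape with `Z` (`M x K`), `gram` (`M x M` symmetric,
#'   entries in \eqn{[-1,1]}) and `identifiable` filled in.
#' @export
z_vectors <- function(model, landscape) {
  stopifnot(inherits(landscape, "fe_landscape"))
  K <- landscape$K
  sa <- sqrt(model$alpha)
  w <- landscape$dets^(-1 / 2)
  tot <- sum(w)
  Th <- vapply(seq_len(K),
               function(k) tanh(landscape$minima[k, ] / sa),
               numeric(model$M))          # M x K
  Th <- matrix(Th, nrow = model$M)
  Z <- sweep(Th, 2, landscape$dets^(-1 / 4), "*") / sqrt(tot)
  gram <- Z %*% t(Z)
  gram <- (gram + t(gram)) / 2
  ident <- TRUE
  if (model$M >= 2) {
    for (l in seq_len(model$M - 1)) {
      for (m in seq(l + 1, model$M)) {
        if (max(abs(Z[l, ] - Z[m, ])) <= 1e-8) ident <- FALSE
      }
    }
  }
  landscape$Z <- Z
  landscape$gram <- gram
  landscape$identifiable <- ident
  landscape
}

#' Separation constants for community detection
#'
#' The level-window clustering needs the limiting correlation levels of
#' distinct groups to be separated. For a high-temperature limit matrix `A`
#' (the size-adjusted `K` of [pair_limit_high()], or any symmetric
#' positive-definite matrix such as \eqn{H^{-1}} itself) the constants are
#' \deqn{\eta = \min_{l \ne m}\{\max(A_{ll}, A_{mm}) - A_{lm}\}, \quad
#'   \xi = \min_{l \ne m}\{|A_{ll} - A_{mm}| : A_{ll} \ne A_{mm}\},}
#' and \eqn{\delta = \min(\eta, \xi)}. For a low-temperature landscape the
#' constants are built on the `Z`-vector Gram matrix:
#' \deqn{\eta = \min\{| \|Z_l\|^2 - \|Z_m\|^2 | : \|Z_l\| \ne \|Z_m\|\}, \quad
#'   \xi = \min\{ \|Z_l\|^2 - \langle Z_l, Z_m\rangle : \|Z_l\| = \|Z_m\|\},}
#' and \eqn{\gamma = \min(\eta, \xi)}. A minimum over an empty set is
#' \eqn{+\infty} (for `M = 1` both constants are \eqn{+\infty} and detection
#' trivially assigns a single class).
#'
#' @param x A `"high_temp_theory"`, an `"fe_landscape"` (with `Z` filled), or
#'   a symmetric matrix treated as a high-temperature limit matrix.
#' @param tol Tolerance for calling two diagonal entries (or norms) equal.
#' @param ... Unused.
#' @return An object of class `"separation_constants"`: list with `eta`,
#'   `xi`, `delta` (their minimum — the paper-facing \eqn{\delta} or
#'   \eqn{\gamma} depending on regime) and `regime`.
#' @examples
#' th <- pair_limit_high(three_party_model())
#' separation_constants(th$Hinv)    # eta = 3.1379, xi = 1.0345
#' @export
separation_constants <- function(x, ...) UseMethod("separation_constants")

#' @rdname separation_constants
#' @export
separation_constants.matrix <- function(x, tol = 1e-9, ...) {
  A <- x
  M <- nrow(A)
  if (M < 2) {
    return(structure(list(eta = Inf, xi = Inf, delta = Inf, regime = "high"),
                     class = "separation_constants"))
  }
  d <- diag(A)
  eta <- Inf; xi <- Inf
  for (l in seq_len(M - 1)) {
    for (m in seq(l + 1, M)) {
      eta <- min(eta, max(d[l], d[m]) - A[l, m])
      if (abs(d[l] - d[m]) > tol) xi <- min(xi, abs(d[l] - d[m]))
    }
  }
  if (eta <= 0) {
    stop("non-positive eta: input is not a valid limit matrix ",
         "(off-diagonal >= both diagonals)")
  }
  structure(list(eta = eta, xi = xi, delta = min(eta, xi), regime = "high"),
            class = "separation_constants")
}

#' @rdname separation_constants
#' @export
separation_constants.high_temp_theory <- function(x, tol = 1e-9, ...) {
  separation_constants(x$limit_matrix, tol = tol)
}

#' @rdname separation_constants
#' @export
separation_constants.fe_landscape <- function(x, tol = 1e-9, ...) {
  if (is.null(x$gram)) stop("landscape has no Z vectors; run z_vectors() first")
  M <- nrow(x$gram)
  if (M < 2) {
    return(structure(list(eta = Inf, xi = Inf, delta = Inf, regime = "low"),
                     class = "separation_constants"))
  }
  nrm <- diag(x$gram)
  eta <- Inf; xi <- Inf
  for (l in seq_len(M - 1)) {
    for (m in seq(l + 1, M)) {
      if (abs(nrm[l] - nrm[m]) > tol) {
        eta <- min(eta, abs(nrm[l] - nrm[m]))
      } else {
        xi <- min(xi, abs(nrm[l] - x$gram[l, m]))
      }
    }
  }
  structure(list(eta = eta, xi = xi, delta = min(eta, xi), regime = "low"),
            class = "separation_constants")
}

#' @export
print.separation_constants <- function(x, ...) {
  nm <- if (x$regime == "low") "gamma" else "delta"
  cat(sprintf("Separation constants (%s regime): eta = %s, xi = %s, %s = %s\n",
              x$regime, format(x$eta), format(x$xi), nm, format(x$delta)))
  invisible(x)
}

#' Failure-probability bound for community detection
#'
#' Upper bound on the probability that the level-window algorithm does not
#' recover the group partition from `n` observations:
#' \deqn{e_{high}(n) = N^2 (n+1)^2 \exp\{-\tfrac18 (\delta/(8N))^2 n\}, \quad
#'   e_{low}(n) = N^2 (n+1)^2 \exp\{-\tfrac18 (\gamma/8)^2 n\}.}
#' The bound combines a union bound over pairs with a Sanov-type tail for the
#' empirical pair correlations; it exceeds 1 (is vacuous) for small `n`, and
#' in the high temperature regime its exponent scales as \eqn{1/N^2} — the
#' price of resolving correlation levels that are themselves of order 1/N.
#'
#' @param regime `"high"` or `"low"`.
#' @param N Population size.
#' @param n Number of observations (vectorised).
#' @param sep A `"separation_constants"` object, or the numeric value of
#'   \eqn{\delta} (high) / \eqn{\gamma} (low).
#' @return Numeric vector of bounds (not truncated at 1).
#' @examples
#' failure_bound("high", N = 10, n = 0, sep = 1)   # 100
#' @seealso [min_observations()]
#' @export
failure_bound <- function(regime = c("high", "low"), N, n, sep) {
  regime <- match.arg(regime)
  s <- if (inherits(sep, "separation_constants")) sep$delta else as.numeric(sep)
  if (!is.finite(s) || s <= 0) stop("'sep' must be a finite positive constant")
  eps <- if (regime == "high") s / (8 * N) else s / 8
  exp(2 * log(N) + 2 * log1p(n) - n * eps^2 / 8)
}

#' Smallest sample size with failure bound below a target
#'
#' Inverts [failure_bound()]: returns the smallest `n` beyond the bound's
#' turning point with \eqn{e(n) \le \epsilon} (and \eqn{e(n-1) > \epsilon}).
#' The bound is a conservative sufficient condition — in practice far fewer
#' observations usually suffice — so treat the result as a guarantee level,
#' not a practical requirement (`attr(, "conservative")` reminds of this).
#'
#' @inheritParams failure_bound
#' @param eps Target failure probability in (0, 1).
#' @return Integer-valued numeric sample size `n*` (a double, since the
#'   high-temperature bound can require counts beyond integer range), with
#'   attribute `conservative = TRUE`.
#' @examples
#' min_observations("low", N = 20, sep = 1.5865, eps = 0.2)
#' @export
min_observations <- function(regime = c("high", "low"), N, sep, eps) {
  regime <- match.arg(regime)
  if (eps <= 0 || eps >= 1) stop("'eps' must be in (0, 1)")
  s <- if (inherits(sep, "separation_constants")) sep$delta else as.numeric(sep)
  if (!is.finite(s) || s <= 0) stop("'sep' must be a finite positive constant")
  e <- if (regime == "high") s / (8 * N) else s / 8
  c0 <- e^2 / 8
  logb <- function(n) 2 * log(N) + 2 * log1p(n) - c0 * n
  ## log-derivative 2/(n+1) - c0 changes sign at the turning point
  n_turn <- max(1, ceiling(2 / c0 - 1))
  hi <- n_turn
  while (logb(hi) > log(eps)) {
    hi <- hi * 2
    if (hi > 1e18) stop("failure bound does not reach eps (overflow guard)")
  }
  lo <- n_turn
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (logb(mid) <= log(eps)) hi <- mid else lo <- mid
  }
  structure(as.numeric(hi), conservative = TRUE)
}

#' Correlation levels and window half-width for detection
#'
#' Packages the regime-specific input of [identify_groups()]: the distinct
#' limiting correlation values ("levels", sorted decreasing) and the
#' half-width of the closed window around each level. High temperature:
#' levels are the distinct diagonal entries of the size-adjusted limit
#' matrix divided by `N`, half-width \eqn{\delta/(4N)}. Low temperature:
#' levels are the distinct squared norms \eqn{\|Z_l\|^2}, half-width
#' \eqn{\gamma/4}. Consecutive levels are separated by more than twice the
#' half-width by construction, so windows never overlap.
#'
#' @param x A `"high_temp_theory"` or an `"fe_landscape"` (with `Z` filled).
#' @param N Population size (required for the high-temperature scaling; taken
#'   from the theory object when omitted).
#' @param tol Tolerance for grouping equal levels.
#' @return An object of class `"level_spec"`: list with `levels` (decreasing,
#'   correlation scale), `halfwidth`, `regime`, and `groups_at_level` (which
#'   model groups share each level, when known).
#' @export
level_spec <- function(x, N = NULL, tol = 1e-9) {
  if (inherits(x, "high_temp_theory")) {
    if (is.null(N)) N <- x$N
    diags <- diag(x$limit_matrix)
    sep <- separation_constants(x, tol = tol)
    lev_raw <- diags / N
    hw <- sep$delta / (4 * N)
    regime <- "high"
  } else if (inherits(x, "fe_landscape")) {
    if (is.null(x$gram)) stop("landscape has no Z vectors; run z_vectors() first")
    if (!x$identifiable) {
      stop("groups are not identifiable (two Z vectors coincide); ",
           "low-temperature detection refuses to build a level spec")
    }
    diags <- diag(x$gram)
    sep <- separation_constants(x, tol = tol)
    lev_raw <- diags
    hw <- sep$delta / 4
    regime <- "low"
  } else {
    stop("'x' must be a high_temp_theory or fe_landscape object")
  }
  if (!is.finite(hw)) {
    ## M = 1: a single level with an everything-window
    lev <- lev_raw[1]
    return(structure(list(levels = lev, halfwidth = Inf, regime = regime,
                          groups_at_level = list(seq_along(diags)),
                          sep = sep),
                     class = "level_spec"))
  }
  ord <- order(lev_raw, decreasing = TRUE)
  lev <- c(); groups <- list()
  for (l in ord) {
    if (length(lev) && abs(lev_raw[l] - lev[length(lev)]) <= tol * max(1, abs(lev[length(lev)]))) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], l)
    } else {
      lev <- c(lev, lev_raw[l])
      groups[[length(groups) + 1]] <- l
    }
  }
  structure(list(levels = lev, halfwidth = hw, regime = regime,
                 groups_at_level = groups, sep = sep),
            class = "level_spec")
}

#' @export
print.level_spec <- function(x, ...) {
  cat(sprintf("Level spec (%s regime): %d level(s), halfwidth %s\n",
              x$regime, length(x$levels), format(x$halfwidth)))
  for (u in seq_along(x$levels)) {
    cat(sprintf("  level %d: %s  (groups %s)\n", u, format(x$levels[u]),
                paste(x$groups_at_level[[u]], collapse = ",")))
  }
  invisible(x)
}
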