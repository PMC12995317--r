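# Shared fixtures and independent reference computations. The reference
# functions here are deliberately written from the definitions (direct sums
# over configurations, fixed-point iteration, central differences) and share
# no code with the package internals they check.

# antagonistic two-group low-temperature model: strong within-group cohesion,
# weak cross-group antagonism; satisfies the Z-vector identifiability
# assumption (the aligned-coupling variant does not)
low_temp_model <- function(sizes = c(10, 10)) {
  block_spin(sizes, matrix(c(1.5, -0.1, -0.1, 1.5), 2, 2))
}

high_temp_model_2g <- function(sizes = c(3, 3)) {
  block_spin(sizes, matrix(c(0.6, 0.1, 0.1, 0.4), 2, 2))
}

# Curie-Weiss magnetization m* solving m = tanh(beta m), by damped
# fixed-point iteration (independent of the package's optimizer)
cw_magnetization <- function(beta, tol = 1e-12) {
  m <- 0.9
  for (k in 1:10000) {
    m_new <- tanh(beta * m)
    if (abs(m_new - m) < tol) break
    m <- m_new
  }
  m_new
}

# direct double-sum Hamiltonian from the definition (includes i = j terms)
hamiltonian_direct <- function(model, x) {
  tot <- 0
  for (i in seq_len(model$N)) {
    for (j in seq_len(model$N)) {
      l <- model$labels[i]; m <- model$labels[j]
      tot <- tot + model$J[l, m] /
        sqrt(model$sizes[l] * model$sizes[m]) * x[i] * x[j]
    }
  }
  -tot / 2
}

# full-configuration Gibbs probabilities by direct 2^N enumeration
enumerate_probs <- function(model) {
  X <- as.matrix(expand.grid(rep(list(c(-1, 1)), model$N)))
  dimnames(X) <- NULL
  e <- vapply(seq_len(nrow(X)),
              function(r) hamiltonian_direct(model, X[r, ]), numeric(1))
  w <- exp(-e - max(-e))
  list(configs = X, probs = w / sum(w))
}

# central-difference gradient and Hessian of a scalar function
num_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- replace(numeric(length(x)), k, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

num_hessian <- function(f, x, h = 1e-4) {
  M <- length(x)
  H <- matrix(0, M, M)
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      ea <- replace(numeric(M), a, h); eb <- replace(numeric(M), b, h)
      H[a, b] <- (f(x + ea + eb) - f(x + ea - eb) -
                    f(x - ea + eb) + f(x - ea - eb)) / (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

# random symmetric positive definite matrix
random_spd <- function(M) {
  A <- matrix(rnorm(M * M), M, M)
  crossprod(A) + diag(M) * 0.1
}
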