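# Independent numerical oracles used by the tests. These share no code with
# the implementation paths they check.

# Crank-Nicolson integration of the 1-D Ito Fokker-Planck equation
#   dp/dt = -d(a p)/dx + d^2(D p)/dx^2
# on a cell-centered grid with zero-flux-free (absorbing far-field) edges.
# `a_fun`, `D_fun` take coordinates; returns cell masses (p * h).
cn_fpe_solve <- function(a_fun, D_fun, x_centers, p0_mass, t_end, n_steps) {
  n <- length(x_centers)
  h <- x_centers[2] - x_centers[1]
  a <- a_fun(x_centers)
  D <- D_fun(x_centers)
  # generator L acting on densities: (L p)_i =
  #   [D_{i+1} p_{i+1} - 2 D_i p_i + D_{i-1} p_{i-1}]/h^2
  #   - [a_{i+1} p_{i+1} - a_{i-1} p_{i-1}]/(2 h)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    L[i, i] <- -2 * D[i] / h^2
    if (i > 1) L[i, i - 1] <- D[i - 1] / h^2 + a[i - 1] / (2 * h)
    if (i < n) L[i, i + 1] <- D[i + 1] / h^2 - a[i + 1] / (2 * h)
  }
  dt <- t_end / n_steps
  I <- diag(n)
  Aimp <- I - dt / 2 * L
  Bexp <- I + dt / 2 * L
  M <- solve(Aimp, Bexp)
  p <- p0_mass / h
  for (s in seq_len(n_steps)) p <- M %*% p
  as.numeric(p) * h
}

# Euler-Maruyama paths of dx = a(x) dt + sqrt(2 D(x)) dW (vectorized)
em_sde_paths <- function(a_fun, D_fun, x0, t_end, dt, n_paths) {
  x <- rep(x0, n_paths)
  steps <- round(t_end / dt)
  for (s in seq_len(steps)) {
    x <- x + a_fun(x) * dt + sqrt(2 * pmax(D_fun(x), 0) * dt) * rnorm(n_paths)
  }
  x
}

# Interacting mean-field EM ensemble: the drift uses the running empirical
# ensemble mean (oracle for the non-linear benchmark).
em_meanfield_paths <- function(nu, lambda, D, x0, t_end, dt, n_paths) {
  x <- rep(x0, n_paths)
  steps <- round(t_end / dt)
  sig <- sqrt(2 * D * dt)
  for (s in seq_len(steps)) {
    m1 <- mean(x)
    x <- x + (-nu * x - lambda * (x - m1)) * dt + sig * rnorm(n_paths)
  }
  x
}

# deterministic propagation of a 1-D lattice master equation defined by a
# conditional transition triple (used to check kernels without Monte Carlo)
propagate_triple_1d <- function(mass, triple, reflective = FALSE) {
  n <- length(mass)
  un_plus <- (1 - triple$rest) * triple$p_plus
  un_minus <- (1 - triple$rest) * triple$p_minus
  out <- mass * triple$rest
  right <- mass * un_plus
  left <- mass * un_minus
  out[2:n] <- out[2:n] + right[1:(n - 1)]
  out[1:(n - 1)] <- out[1:(n - 1)] + left[2:n]
  if (reflective) {
    out[n] <- out[n] + right[n]
    out[1] <- out[1] + left[1]
  }
  out
}

# small convenience: per-run summary moments along one axis
run_axis_stats <- function(per_run, tname, domain, species = "A", axis = 1) {
  t(vapply(per_run, function(r) {
    sm <- state_moments(r[[tname]]$counts[[species]], domain)
    c(mean = sm$mean[axis], var = sm$covariance[axis, axis])
  }, numeric(2)))
}
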