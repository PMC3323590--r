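# Transition kernels: first-passage splitting probabilities, exit-time
# moments, the canonical discrete-time step, rescaled probabilities for
# arbitrary admissible steps, and the Fokker-Planck comparison kernel.

# Random parameter triples: each of drift, diffusivity and spacing spans
# more than six orders of magnitude, with the cell Peclet number held in
# [1e-2, 1e2] where the conditional-probability representation can carry
# full relative precision (at |Peclet| << 1e-6 the jump asymmetry falls
# below the resolution of a double near 1/2).
random_fields <- function(n, seed = 424243) {
  set.seed(seed)
  spacing <- 10^runif(n, -2, 1)
  diffusivity <- 10^runif(n, -3, 3)
  peclet <- 10^runif(n, -2, 2) * sample(c(-1, 1), n, TRUE)
  list(drift = peclet * diffusivity / spacing,
       diffusivity = diffusivity, spacing = spacing)
}

test_that("splitting probabilities are symmetric, normalized and monotone", {
  sp <- fpt_splitting_probabilities(0, 2.3, 0.7)
  expect_identical(sp$p_plus, 0.5)
  expect_identical(sp$p_minus, 0.5)

  rf <- random_fields(300)
  for (k in c(1, 57, 200)) {
    a <- rf$drift[k]; D <- rf$diffusivity[k]; h <- rf$spacing[k]
    pp <- fpt_splitting_probabilities(a, D, h)
    pm <- fpt_splitting_probabilities(-a, D, h)
    expect_equal(pp$p_plus, pm$p_minus, tolerance = 1e-14)
    expect_equal(pp$p_plus + pp$p_minus, 1, tolerance = 1e-15)
  }
  # monotone in drift at fixed D, h
  drifts <- seq(-5, 5, length.out = 41)
  p <- fpt_splitting_probabilities(drifts, 1, 1)$p_plus
  expect_true(all(diff(p) > 0))
  # extreme Peclet saturates without numeric failure
  ext <- fpt_splitting_probabilities(c(-1e6, 1e6), 1e-3, 1)
  expect_equal(ext$p_plus, c(0, 1))
})

test_that("exit-time moments match closed forms and limits", {
  # zero drift: mean h^2/(2D), variance h^4/(6D^2)
  m <- fpt_exit_time_moments(0, 0.5, 1)
  expect_equal(m$mean, 1)
  expect_equal(m$variance, 1 / 6 / 0.25)

  # ballistic limit: |a| -> infinity at fixed D
  m2 <- fpt_exit_time_moments(1e8, 2, 0.5)
  expect_equal(m2$mean, 0.5 / 1e8, tolerance = 1e-10)
  # zero diffusivity: exact ballistic values
  m3 <- fpt_exit_time_moments(-4, 0, 2)
  expect_identical(m3$mean, 0.5)
  expect_identical(m3$variance, 0)

  # CTRW identities recover the input coefficients from splitting
  # probabilities + exit moments: v = h (p+ - p-) / mean,
  # D = [h^2 - (h(p+-p-))^2] / (2 mean) + (h(p+-p-))^2 var / (2 mean^3)
  rf <- random_fields(50, seed = 99)
  for (k in seq_len(50)) {
    a <- rf$drift[k]; D <- rf$diffusivity[k]; h <- rf$spacing[k]
    pe <- abs(a) * h / D
    if (pe > 500) next  # splitting probability saturates to 1 in doubles
    sp <- fpt_splitting_probabilities(a, D, h)
    mo <- fpt_exit_time_moments(a, D, h)
    m1 <- h * (sp$p_plus - sp$p_minus)
    v_rec <- m1 / mo$mean
    D_rec <- (h^2 - m1^2) / (2 * mo$mean) + m1^2 * mo$variance / (2 * mo$mean^3)
    expect_equal(v_rec, a, tolerance = 1e-9)
    expect_equal(D_rec, D, tolerance = 1e-9)
  }
})

test_that("canonical step reproduces the splitting probabilities exactly", {
  rf <- random_fields(1000)
  cs <- canonical_step(rf$drift, rf$diffusivity, 1)
  expect_true(all(cs$rest >= 0 & cs$rest < 1))
  for (k in c(2, 10, 333, 999)) {
    a <- rf$drift[k]; D <- rf$diffusivity[k]; h <- rf$spacing[k]
    cs1 <- canonical_step(a, D, h)
    tr <- rescaled_probabilities(a, D, h, cs1$timestep)
    sp <- fpt_splitting_probabilities(a, D, h)
    expect_equal(tr$p_plus, sp$p_plus, tolerance = 1e-12)
    expect_equal(tr$rest, cs1$rest, tolerance = 1e-12)
  }
})

test_that("rescaled probabilities satisfy the moment identities exactly", {
  rf <- random_fields(200, seed = 7)
  set.seed(8)
  for (k in seq_len(200)) {
    a <- rf$drift[k]; D <- rf$diffusivity[k]; h <- rf$spacing[k]
    dtc <- canonical_step(a, D, h)$timestep
    # for Peclet > 2 the conditional probabilities only stay in [0, 1] for
    # dt >= (|a| h - 2 D)/a^2; sample admissible steps only
    dt_lo <- max(1e-3 * dtc, (abs(a) * h - 2 * D) / a^2)
    for (frac in runif(3)) {
      dt <- dt_lo + frac * (dtc - dt_lo)
      tr <- rescaled_probabilities(a, D, h, dt)
      eff <- ctrw_effective_coefficients(tr$p_minus, tr$p_plus, tr$rest,
                                         dt, h)
      expect_equal(eff$drift, a, tolerance = 1e-10)
      expect_equal(eff$diffusivity, D, tolerance = 1e-10)
      # unconditional probabilities are normalized
      expect_equal((1 - tr$rest) * (tr$p_minus + tr$p_plus) + tr$rest, 1,
                   tolerance = 1e-15)
    }
  }
})

test_that("zero-drift branch joins the general branch seamlessly", {
  for (h in c(0.1, 1)) for (D in c(0.3, 4)) {
    m0 <- fpt_exit_time_moments(0, D, h)
    mp <- fpt_exit_time_moments(1e-12, D, h)
    expect_equal(mp$mean, m0$mean, tolerance = 1e-8)
    expect_equal(mp$variance, m0$variance, tolerance = 1e-8)
    c0 <- canonical_step(0, D, h)
    cp <- canonical_step(-1e-12, D, h)
    expect_equal(cp$timestep, c0$timestep, tolerance = 1e-8)
    expect_equal(cp$rest, c0$rest, tolerance = 1e-8)
    # and across the series switchover itself
    b <- 0.02 * 2 * D / h   # drift at the threshold Peclet
    lo <- fpt_exit_time_moments(b * (1 - 1e-9), D, h)
    hi <- fpt_exit_time_moments(b * (1 + 1e-9), D, h)
    expect_equal(lo$variance, hi$variance, tolerance = 1e-8)
  }
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(fpt_splitting_probabilities(0, 0, 1), "immobile")
  expect_error(fpt_exit_time_moments(0, 0, 1), "immobile")
  expect_error(rescaled_probabilities(1, 1, -1, 0.1), "spacing")
  expect_error(rescaled_probabilities(1, 1, 1, 10), "timestep too large")
  # conditional probability out of range at a too-small step with high Peclet
  expect_error(rescaled_probabilities(50, 1, 1, 1e-6), "timestep too large")
  expect_error(fpe_probabilities(5, 1, 1, 0.01), "unstable")
  expect_error(fpt_splitting_probabilities(1, -0.1, 1), "non-negative")
})

test_that("FPE kernel: symmetry, normalization and homogeneous reduction", {
  tr <- fpe_probabilities(0, 1, 1, 0.05)
  expect_equal(tr$p_plus, 0.5)
  expect_equal(tr$rest, 1 - 2 * 0.05)
  expect_equal((1 - tr$rest) * (tr$p_plus + tr$p_minus) + tr$rest, 1)

  hom <- list(drift = rep(0.8, 5), diffusivity = rep(1.2, 5))
  tri <- fpe_inhomogeneous_probabilities(hom, hom, hom, 1, 0.1)
  ref <- fpe_probabilities(0.8, 1.2, 1, 0.1)
  expect_equal(tri$p_plus, rep(ref$p_plus, 5))
  expect_equal(tri$rest, rep(ref$rest, 5))
})

test_that("FPT and FPE unconditional probabilities differ at second order", {
  a <- 1.2; D <- 0.9; h <- 1.1   # Peclet < 2 keeps the FPE kernel stable
  dt0 <- canonical_step(a, D, h)$timestep / 2
  diffs <- vapply(0:8, function(k) {
    dt <- dt0 / 2^k
    fpt <- rescaled_probabilities(a, D, h, dt)
    fpe <- fpe_probabilities(a, D, h, dt)
    abs((1 - fpt$rest) * fpt$p_plus - (1 - fpe$rest) * fpe$p_plus)
  }, numeric(1))
  orders <- log2(diffs[-length(diffs)] / diffs[-1])
  expect_true(all(orders >= 2 - 1e-6))
})

test_that("inhomogeneous FPE kernel agrees with a fine-grid deterministic solve", {
  # linear diffusivity profile, zero drift, reflective lattice
  n <- 30; h <- 0.1
  x <- (seq_len(n) - (n + 1) / 2) * h
  Dfun <- function(x) 1 + 0.3 * x
  a <- rep(0, n); D <- Dfun(x)
  dt <- 0.2 * h^2 / max(D)
  ghost <- function(v) c(v[1], v, v[n])
  av <- ghost(a); Dv <- ghost(D)
  idx <- 2:(n + 1)
  tri <- fpe_inhomogeneous_probabilities(
    left = list(drift = av[idx - 1], diffusivity = Dv[idx - 1]),
    center = list(drift = av[idx], diffusivity = Dv[idx]),
    right = list(drift = av[idx + 1], diffusivity = Dv[idx + 1]),
    spacing = h, timestep = dt)
  mass <- rep(0, n); mass[n %/% 2] <- 1
  steps <- 60
  for (s in seq_len(steps)) mass <- propagate_triple_1d(mass, tri, reflective = TRUE)

  fine <- 10
  xf <- (seq_len(n * fine) - (n * fine + 1) / 2) * (h / fine)
  p0 <- rep(0, n * fine)
  src_lo <- (n %/% 2 - 1) * fine + 1
  p0[src_lo:(src_lo + fine - 1)] <- 1 / fine
  ref_f <- cn_fpe_solve(function(x) 0 * x, Dfun, xf, p0, steps * dt,
                        n_steps = steps * 10)
  ref <- vapply(seq_len(n), function(i)
    sum(ref_f[((i - 1) * fine + 1):(i * fine)]), numeric(1))
  # interior agreement (the coarse kernel is O(h^2))
  interior <- 5:(n - 4)
  expect_lt(max(abs(mass[interior] - ref[interior])), 5e-3)
  expect_gt(stats::cor(mass[interior], ref[interior]), 0.9999)
})

test_that("kernel statistics match an Euler-Maruyama first-passage ensemble", {
  set.seed(20240917)
  a <- 1; D <- 1; h <- 1
  em <- em_first_passage(a, D, h, n_paths = 2e4, dt = 2e-4)
  sp <- fpt_splitting_probabilities(a, D, h)
  mo <- fpt_exit_time_moments(a, D, h)
  expect_lt(abs(em$p_plus - sp$p_plus) / em$p_plus_se, 3)
  expect_lt(abs(em$mean_exit - mo$mean) / em$mean_exit_se, 3)
})

test_that("canonical discrete walk reproduces drift and diffusivity", {
  set.seed(5150)
  a <- 2; D <- 1; h <- 0.5
  cs <- canonical_step(a, D, h)
  sp <- fpt_splitting_probabilities(a, D, h)
  mc <- lattice_walk_moments(sp$p_plus, cs$rest, cs$timestep, h,
                             n_steps = 300, n_walkers = 4e4)
  expect_lt(abs(mc$drift - a) / mc$drift_se, 3)
  expect_lt(abs(mc$diffusivity - D) / mc$diffusivity_se, 3)
})
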