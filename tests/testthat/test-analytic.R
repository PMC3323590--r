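# Validation-suite solutions: closed forms, their oracles, the RMSE metric
# and the migration model components.

test_that("gaussian solution is normalized with the correct mode", {
  dom <- simulation_domain(40, 64, "outflow")
  ref <- gaussian_solution(dom, c(2, 2), c(1, 1), 1e4, 2)
  expect_lt(abs(sum(ref) - 1e4) / 1e4, 1e-6)
  mode_idx <- which(ref == max(ref), arr.ind = TRUE)
  mode_pos <- cell_center_coordinates(mode_idx, dom)
  expect_true(all(abs(mode_pos - c(4, 4)) <= dom$spacing / 2 + 1e-12))
  # time zero collapses to the source cell
  ref0 <- gaussian_solution(dom, c(2, 2), c(1, 1), 1e4, 0, origin = c(0, 0))
  expect_equal(max(ref0), 1e4)
  expect_equal(sum(ref0 > 0), 1)
})

test_that("gaussian solution agrees with a Crank-Nicolson integration", {
  # the 2-D solution factorizes; evolve the x-marginal from a smooth early
  # state on an 8x finer grid and compare with the closed form later on
  dom <- simulation_domain(30, 50, "outflow")
  a <- 1; D <- 1; t0 <- 0.5; tt <- 1.5
  h <- dom$spacing
  ref <- gaussian_solution(dom, c(a, 0), c(D, D), 1, tt)
  marg <- rowSums(ref)
  fine <- 8
  nf <- 50 * fine
  hf <- h / fine
  # fine cells tile the coarse cells exactly
  xf <- min(axis_coordinates(dom, 1)) - h / 2 + (seq_len(nf) - 0.5) * hf
  p0 <- stats::pnorm(xf + hf / 2, a * t0, sqrt(2 * D * t0)) -
    stats::pnorm(xf - hf / 2, a * t0, sqrt(2 * D * t0))
  sol <- cn_fpe_solve(function(x) rep(a, length(x)),
                      function(x) rep(D, length(x)), xf, p0, tt - t0,
                      n_steps = 800)
  coarse <- vapply(seq_len(50), function(i)
    sum(sol[((i - 1) * fine + 1):(i * fine)]), numeric(1))
  interior <- which(marg > 1e-4 * max(marg))
  expect_lt(max(abs(marg[interior] - coarse[interior]) / max(marg)), 1e-3)
})

test_that("GBM solution is normalized and collapses as noise vanishes", {
  dom <- simulation_domain(40, 64, origin_shift = c(40, 40))
  ref <- gbm_solution(dom, c(0.05, 0.05), c(0.07, 0.07), 1e4, 1,
                      origin = c(40, 40))
  expect_lt(abs(sum(ref) - 1e4) / 1e4, 1e-5)
  # vanishing noise concentrates mass on the deterministic trajectory
  tiny <- gbm_solution(dom, c(0.05, 0.05), c(1e-4, 1e-4), 1e4, 1,
                       origin = c(40, 40))
  target <- 40 * exp(0.05)
  peak <- cell_center_coordinates(which(tiny == max(tiny), arr.ind = TRUE),
                                  dom)
  expect_true(all(abs(peak - target) <= dom$spacing / 2 + 1e-9))
  expect_gt(max(tiny) / 1e4, 0.99)
  expect_error(gbm_solution(simulation_domain(40, 64), c(0, 0), c(1, 1),
                            1, 1, origin = c(1, 1)), "positive")
})

test_that("GBM quantiles match an Euler-Maruyama ensemble", {
  dom <- simulation_domain(40, 64, origin_shift = c(40, 40))
  g <- 0.05; b <- 0.07; tt <- 1
  ref <- gbm_solution(dom, c(g, g), c(b, b), 1e4, tt, origin = c(40, 40))
  q_ref <- state_quantiles(ref, dom, 1, c(0.1, 0.5, 0.9))
  set.seed(321)
  n <- 4e4
  x <- em_sde_paths(function(x) g * x, function(x) b^2 * x^2 / 2,
                    40, tt, 1e-3, n)
  # bin the EM sample onto the lattice so both sides share the
  # representation, then compare interpolated quantiles
  edges <- c(axis_coordinates(dom, 1) - dom$spacing / 2,
             max(axis_coordinates(dom, 1)) + dom$spacing / 2)
  counts <- hist(x, breaks = edges, plot = FALSE)$counts
  emp <- matrix(0, 64, 64); emp[, 32] <- counts
  q_emp <- state_quantiles(emp, dom, 1, c(0.1, 0.5, 0.9))
  # asymptotic SE of a sample quantile, via the log-normal density
  mu <- log(40) + (g - b^2 / 2) * tt; sd_ln <- b * sqrt(tt)
  for (k in seq_along(q_ref)) {
    p <- c(0.1, 0.5, 0.9)[k]
    dens <- stats::dlnorm(q_ref[k], mu, sd_ln)
    se <- sqrt(p * (1 - p) / n) / dens
    expect_lt(abs(q_emp[k] - q_ref[k]), 3 * se + dom$spacing / 20)
  }
})

test_that("OU moments match a Lyapunov ODE oracle", {
  A <- matrix(c(1, 0.4, 0.6, 1.3), 2, 2)
  Dv <- c(0.8, 1.2)
  x0 <- c(0.5, -0.25)
  mom <- ou_moments(A, Dv, 0.9, origin = x0)
  rhs <- function(t, y, parms) {
    m <- y[1:2]; S <- matrix(y[3:6], 2, 2)
    dm <- -A %*% m
    dS <- -A %*% S - S %*% t(A) + diag(2 * Dv)
    list(c(dm, as.numeric(dS)))
  }
  sol <- deSolve::ode(c(x0, rep(0, 4)), c(0, 0.9), rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  expect_lt(max(abs(mom$mean - sol[2, 2:3])), 1e-8)
  expect_lt(max(abs(as.numeric(mom$covariance) - sol[2, 4:7])), 1e-8)
  # degenerate limits
  m0 <- ou_moments(A, Dv, 0, origin = x0)
  expect_equal(m0$mean, x0)
  expect_equal(m0$covariance, matrix(0, 2, 2))
  free <- ou_moments(matrix(0, 2, 2), Dv, 0.7)
  expect_equal(free$covariance, diag(2 * Dv * 0.7))
})

test_that("OU solution integrates to the total count", {
  dom <- simulation_domain(12, 64)
  ref <- ou_solution(dom, matrix(c(1, 0.5, 0.5, 1), 2, 2), c(1, 1), 1e4, 1)
  # midpoint rule: normalization holds to O(h^2)
  expect_lt(abs(sum(ref) - 1e4) / 1e4, 1e-3)
})

test_that("nonlinear moments and solution behave at the limits", {
  mom0 <- nonlinear_moments(1, 1, 0.5, 1.5, 0)
  expect_equal(mom0$m1, 1.5)
  expect_equal(mom0$variance, 0)
  momT <- nonlinear_moments(1, 1, 0.5, 1.5, 50)
  expect_equal(momT$m1, momT$asymptotic$m1, tolerance = 1e-12)
  expect_equal(momT$variance, momT$asymptotic$variance, tolerance = 1e-12)
  dom <- simulation_domain(7, 64)
  ref <- nonlinear_solution(dom, 1, 1, 0.5, 1e4, 2, c(1.5, 0))
  expect_lt(abs(sum(ref) - 1e4) / 1e4, 1e-6)
  # mass confined to the immobile-axis source slice
  expect_equal(sum(colSums(ref) > 0), 1)
})

test_that("nonlinear density matches a mean-field particle oracle", {
  nu <- 1; lam <- 1; D <- 0.5; x0 <- 1.5
  set.seed(777)
  n <- 4e4
  for (tt in c(0.5, 2)) {
    x <- em_meanfield_paths(nu, lam, D, x0, tt, 5e-4, n)
    mom <- nonlinear_moments(nu, lam, D, x0, tt)
    expect_lt(abs(mean(x) - mom$m1) / (stats::sd(x) / sqrt(n)), 3.5)
    v_se <- stats::var(x) * sqrt(2 / (n - 1))
    expect_lt(abs(stats::var(x) - mom$variance) / v_se, 3.5)
    # pointwise density at three probe coordinates
    h <- 0.12
    for (xq in c(mom$m1, mom$m1 + 0.3, mom$m1 - 0.5)) {
      p_emp <- mean(abs(x - xq) < h / 2)
      p_th <- stats::pnorm(xq + h / 2, mom$m1, sqrt(mom$variance)) -
        stats::pnorm(xq - h / 2, mom$m1, sqrt(mom$variance))
      se <- sqrt(p_th * (1 - p_th) / n)
      expect_lt(abs(p_emp - p_th), 3.5 * se + 2e-4)
    }
  }
})

test_that("the first-moment hook reproduces direct weighted averages", {
  dom <- simulation_domain(8, 8)
  m <- matrix(0, 8, 8); m[3, 4] <- 17
  st <- lattice_state(m)
  expect_equal(nonlinear_drift_hook(st, dom, 1),
               cell_center_coordinates(c(3, 4), dom)[1, 1])
  # symmetric two-cell configuration: midpoint
  m2 <- matrix(0, 8, 8); m2[3, 4] <- 5; m2[7, 4] <- 5
  expect_equal(nonlinear_drift_hook(lattice_state(m2), dom, 1),
               mean(cell_center_coordinates(rbind(c(3, 4), c(7, 4)),
                                            dom)[, 1]))
  set.seed(4)
  m3 <- matrix(rpois(64, 3), 8, 8)
  st3 <- lattice_state(m3)
  brute <- 0
  for (i in 1:8) for (j in 1:8)
    brute <- brute + m3[i, j] * cell_center_coordinates(c(i, j), dom)[1, 1]
  expect_equal(nonlinear_drift_hook(st3, dom, 1), brute / sum(m3))
  expect_error(nonlinear_drift_hook(lattice_state(matrix(0, 8, 8)), dom),
               "empty")
})

test_that("rmse matches its definition", {
  expect_equal(rmse(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(rmse(matrix(5, 3, 3), matrix(2, 3, 3)), 3)
  expect_equal(rmse(matrix(c(0, 2), 1), matrix(c(0, 0), 1)), sqrt(2))
  expect_error(rmse(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("migration field honours its limiting regimes", {
  par <- migration_parameters()
  dom <- simulation_domain(par$side_length, 32)
  n <- 32
  # empty lattice before Slit application: uniform motility, zero drift
  st0 <- lattice_state(list(neuron = matrix(0, n, n)), time = 0)
  f0 <- migration_field(st0, dom, 0, par)
  expect_true(all(f0$diff_x == par$motility))
  expect_true(all(f0$drift_x == 0) && all(f0$drift_y == 0))
  # crowding saturates the field towards zero
  big <- lattice_state(list(neuron = matrix(1e7, n, n)))
  fb <- migration_field(big, dom, 0, par)
  expect_lt(max(fb$diff_x) / par$motility, 1e-3)
  # centered differences are exact on a linear profile
  lin <- field_model(function(domain, state, time, species) {
    xs <- domain$side_length + axis_coordinates(domain, 1)  # positive, slope 1
    list(drift_x = 0, drift_y = 0,
         diff_x = matrix(xs, domain$cells_per_dim, domain$cells_per_dim),
         diff_y = 1)
  })
  fe <- eval_fields(lin, dom, st0, 0)
  gx <- (fe$diff_x[3:n, ] - fe$diff_x[1:(n - 2), ]) / (2 * dom$spacing)
  expect_true(all(abs(gx - 1) < 1e-12))
  # Slit switches on at the application time
  f_pre <- migration_field(st0, dom, par$slit_time - 1, par)
  f_post <- migration_field(st0, dom, par$slit_time, par)
  expect_true(all(f_post$interaction <= f_pre$interaction))
  expect_gt(max(f_post$drift_y), 0)
})

test_that("the asymmetry statistic is signed distance away from the source", {
  dom <- simulation_domain(10, 10)
  m <- matrix(0, 10, 10)
  m[5, 4] <- 10; m[5, 8] <- 10   # symmetric about y = 0 (columns 4 and 8)
  ys <- axis_coordinates(dom, 2)
  expect_equal(ys[4], -ys[8])
  st <- lattice_state(m)
  expect_equal(migration_asymmetry(st, dom, "ymin", species = "A"), 0)
  m2 <- matrix(0, 10, 10); m2[5, 9] <- 3
  expect_gt(migration_asymmetry(lattice_state(m2), dom, "ymin",
                                species = "A"), 0)
  expect_lt(migration_asymmetry(lattice_state(m2), dom, "ymax",
                                species = "A"), 0)
  expect_error(migration_asymmetry(lattice_state(matrix(0, 10, 10)), dom,
                                   species = "A"), "empty")
})
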