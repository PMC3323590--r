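# Independent numerical oracles used to validate the transition kernels.
#
# The Euler-Maruyama first-passage oracle integrates the underlying SDE
# directly and therefore shares no code with the kernels it checks. Exits
# are detected with a Brownian-bridge correction: between two successive
# discrete positions the probability that the continuous path touched a
# barrier is exp(-(b - x0)(b - x1)/(D dt)), which removes the O(sqrt(dt))
# bias of discrete monitoring (essential at large ensemble sizes, where the
# Monte-Carlo error is smaller than that bias).

#' Euler-Maruyama first-passage ensemble
#'
#' Simulates paths of \code{dx = a dt + sqrt(2 D) dW} started at a cell
#' center until first exit at \code{+-spacing}, with Brownian-bridge
#' crossing detection inside each step. Returns ensemble estimates of the
#' splitting probability and the exit-time moments with standard errors.
#'
#' @param drift drift a.
#' @param diffusivity diffusivity D (> 0).
#' @param spacing exit barriers at \code{+-spacing}.
#' @param n_paths number of paths.
#' @param dt integration step.
#' @return list with \code{p_plus}, \code{p_plus_se}, \code{mean_exit},
#'   \code{mean_exit_se}, \code{var_exit}, \code{n_paths}.
#' @export
em_first_passage <- function(drift, diffusivity, spacing,
                             n_paths = 1e5, dt = 1e-5) {
  stopifnot(diffusivity > 0, spacing > 0, n_paths >= 10, dt > 0)
  a <- drift; D <- diffusivity; h <- spacing
  sig <- sqrt(2 * D * dt)
  x <- numeric(n_paths)
  alive <- rep(TRUE, n_paths)
  exit_right <- logical(n_paths)
  exit_time <- numeric(n_paths)
  t <- 0
  while (any(alive)) {
    idx <- which(alive)
    k <- length(idx)
    x0 <- x[idx]
    x1 <- x0 + a * dt + sig * stats::rnorm(k)
    # bridge probabilities of touching each barrier during this step
    pu <- ifelse(x1 >= h | x0 >= h, 1, exp(-(h - x0) * (h - x1) / (D * dt)))
    pl <- ifelse(x1 <= -h | x0 <= -h, 1, exp(-(x0 + h) * (x1 + h) / (D * dt)))
    # at most one barrier is plausibly hit per small step; treat the events
    # as competing: upper wins with pu*(1-pl/2)-style overlap ignored (both
    # probabilities are never simultaneously non-negligible for dt << h^2/D)
    u <- stats::runif(k)
    hit_u <- u < pu
    hit_l <- !hit_u & (stats::runif(k) < pl)
    done <- hit_u | hit_l
    t <- t + dt
    w <- idx[done]
    exit_right[w] <- hit_u[done]
    exit_time[w] <- t
    alive[w] <- FALSE
    x[idx[!done]] <- x1[!done]
  }
  p_hat <- mean(exit_right)
  list(p_plus = p_hat,
       p_plus_se = sqrt(p_hat * (1 - p_hat) / n_paths),
       mean_exit = mean(exit_time),
       mean_exit_se = stats::sd(exit_time) / sqrt(n_paths),
       var_exit = stats::var(exit_time),
       n_paths = n_paths)
}

#' Monte-Carlo moments of the fixed-step lattice walk
#'
#' Simulates walkers on an unbounded 1-D lattice with the given conditional
#' jump probabilities, rest probability and time step, and estimates the
#' effective drift and diffusivity from the displacement moments at the
#' final time. Used as an independent check that a transition triple
#' reproduces its macroscopic coefficients.
#'
#' @param p_plus conditional probability of a rightward jump.
#' @param rest rest probability.
#' @param timestep,spacing walk time step and lattice spacing.
#' @param n_steps number of steps.
#' @param n_walkers ensemble size.
#' @return list with \code{drift}, \code{drift_se}, \code{diffusivity},
#'   \code{diffusivity_se}.
#' @export
lattice_walk_moments <- function(p_plus, rest, timestep, spacing,
                                 n_steps = 400, n_walkers = 1e5) {
  pos <- integer(n_walkers)
  for (s in seq_len(n_steps)) {
    move <- stats::runif(n_walkers) >= rest
    dir <- ifelse(stats::runif(n_walkers) < p_plus, 1L, -1L)
    pos <- pos + ifelse(move, dir, 0L)
  }
  tT <- n_steps * timestep
  disp <- pos * spacing
  m <- mean(disp); v <- stats::var(disp)
  n <- n_walkers
  list(drift = m / tT,
       drift_se = stats::sd(disp) / sqrt(n) / tT,
       diffusivity = v / (2 * tT),
       # SE of the sample variance of a near-Gaussian displacement
       diffusivity_se = v * sqrt(2 / (n - 1)) / (2 * tT))
}

#' Compare kernel predictions with the Euler-Maruyama oracle
#'
#' For each requested Peclet number \code{a h / D}, runs
#' \code{\link{em_first_passage}} and tabulates the kernel's splitting
#' probability and mean exit time against the ensemble estimates with their
#' z-scores.
#'
#' @param peclet numeric vector of Peclet numbers.
#' @param diffusivity diffusivity used for all settings.
#' @param spacing lattice spacing used for all settings.
#' @param n_paths,dt passed to \code{\link{em_first_passage}}.
#' @return data frame with one row per setting.
#' @export
validate_kernels <- function(peclet = c(0, 1, 5), diffusivity = 0.5,
                             spacing = 0.2, n_paths = 1e5, dt = 1e-5) {
  rows <- lapply(peclet, function(pe) {
    a <- pe * diffusivity / spacing
    em <- em_first_passage(a, diffusivity, spacing, n_paths, dt)
    sp <- fpt_splitting_probabilities(a, diffusivity, spacing)
    mo <- fpt_exit_time_moments(a, diffusivity, spacing)
    data.frame(
      peclet = pe, drift = a, diffusivity = diffusivity, spacing = spacing,
      p_plus_kernel = sp$p_plus, p_plus_em = em$p_plus,
      p_plus_z = (em$p_plus - sp$p_plus) / em$p_plus_se,
      mean_exit_kernel = mo$mean, mean_exit_em = em$mean_exit,
      mean_exit_z = (em$mean_exit - mo$mean) / em$mean_exit_se,
      n_paths = n_paths)
  })
  do.call(rbind, rows)
}
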