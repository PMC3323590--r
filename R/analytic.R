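# Closed-form reference solutions for the validation suite.
#
# Each solution returns the expected particle count per lattice cell at a
# given time. Where the density factorizes over the axes
# (homogeneous Gaussian, GBM log-normal, the 1-D non-linear model) the
# expected counts are computed by exact integration of the density over each
# cell (differences of the per-axis CDF at the cell edges), so the counts sum
# to the initial total up to the mass outside the domain. The
# Ornstein-Uhlenbeck density has correlated axes and uses the midpoint rule
# (density at the cell center times the cell measure).

#' Drifting Gaussian solution of homogeneous biased diffusion
#'
#' Expected counts for constant drift and (possibly anisotropic, diagonal)
#' diffusivity starting from a point source: a Gaussian with per-axis mean
#' \code{origin + drift*time} and variance \code{2*diffusivity*time},
#' integrated exactly over each cell.
#'
#' @param domain a \code{\link{simulation_domain}}.
#' @param drift length-2 drift vector.
#' @param diffusivity length-2 diffusivity vector (positive).
#' @param count initial particle count.
#' @param time elapsed time (>= 0); at 0 a point mass at the source cell.
#' @param origin source position.
#' @return N x N matrix of expected counts.
#' @export
gaussian_solution <- function(domain, drift, diffusivity, count, time,
                              origin = c(0, 0)) {
  drift <- rep_len(drift, 2); diffusivity <- rep_len(diffusivity, 2)
  if (time < 0) stop("time must be >= 0", call. = FALSE)
  if (time == 0) return(point_mass_counts(domain, origin, count))
  h <- domain$spacing
  mass <- function(axis) {
    ctr <- axis_coordinates(domain, axis)
    mu <- origin[axis] + drift[axis] * time
    sd <- sqrt(2 * diffusivity[axis] * time)
    stats::pnorm(ctr + h / 2, mu, sd) - stats::pnorm(ctr - h / 2, mu, sd)
  }
  count * outer(mass(1), mass(2))
}

#' Log-normal solution of geometric Brownian motion
#'
#' Expected counts for the multiplicative-noise process with per-axis growth
#' rate g and noise amplitude b (drift \code{g*x}, diffusivity
#' \code{b^2 x^2/2}): \code{log(x)} is normal with mean
#' \code{log(x0) + (g - b^2/2) t} and variance \code{b^2 t}, integrated
#' exactly over each cell. All cell coordinates must be strictly positive.
#'
#' @param domain a \code{\link{simulation_domain}} (shifted to positive
#'   coordinates).
#' @param growth length-2 growth-rate vector.
#' @param volatility length-2 noise-amplitude vector.
#' @param count initial particle count.
#' @param time elapsed time.
#' @param origin initial position (strictly positive).
#' @return N x N matrix of expected counts.
#' @export
gbm_solution <- function(domain, growth, volatility, count, time, origin) {
  growth <- rep_len(growth, 2); volatility <- rep_len(volatility, 2)
  if (any(origin <= 0)) stop("origin must be strictly positive", call. = FALSE)
  lo <- axis_coordinates(domain, 1) - domain$spacing / 2
  if (min(lo) <= 0 || min(axis_coordinates(domain, 2) - domain$spacing / 2) <= 0)
    stop("GBM solution requires strictly positive coordinates; ",
         "shift the domain origin", call. = FALSE)
  if (time == 0) return(point_mass_counts(domain, origin, count))
  h <- domain$spacing
  mass <- function(axis) {
    ctr <- axis_coordinates(domain, axis)
    mu <- log(origin[axis]) + (growth[axis] - volatility[axis]^2 / 2) * time
    sd <- volatility[axis] * sqrt(time)
    stats::plnorm(ctr + h / 2, mu, sd) - stats::plnorm(ctr - h / 2, mu, sd)
  }
  count * outer(mass(1), mass(2))
}

# all particles in the cell containing `origin`
point_mass_counts <- function(domain, origin, count) {
  n <- domain$cells_per_dim
  m <- matrix(0, n, n)
  idx <- nearest_cell_index(origin, domain)
  m[idx[1, 1], idx[1, 2]] <- count
  m
}

# matrix exponential by scaling-and-squaring Taylor series (small matrices)
expm_small <- function(M) {
  nrm <- max(abs(M))
  s <- max(0L, ceiling(log2(max(1, nrm))))
  Ms <- M / 2^s
  E <- diag(nrow(M)); term <- diag(nrow(M))
  for (k in 1:24) {
    term <- term %*% Ms / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Mean and covariance of the Ornstein-Uhlenbeck process
#'
#' For \code{dx = -A x dt + sqrt(2 D) dW} (diagonal noise with per-axis
#' diffusivity D, relaxation matrix A not necessarily diagonal):
#' mean \code{expm(-A t) x0} and covariance
#' \code{integral_0^t expm(-A s) Q expm(-A' s) ds} with \code{Q = 2 diag(D)},
#' evaluated in closed form by Van Loan's block-exponential construction.
#'
#' @param relaxation 2 x 2 relaxation matrix A.
#' @param diffusivity length-2 per-axis diffusivity.
#' @param time elapsed time.
#' @param origin initial position.
#' @return list with components \code{mean} (length 2) and
#'   \code{covariance} (2 x 2).
#' @export
ou_moments <- function(relaxation, diffusivity, time, origin = c(0, 0)) {
  A <- matrix(as.numeric(relaxation), 2, 2)
  Q <- diag(2 * rep_len(diffusivity, 2))
  C <- rbind(cbind(-A, Q), cbind(matrix(0, 2, 2), t(A)))
  Ft <- expm_small(C * time)
  F11 <- Ft[1:2, 1:2]; F12 <- Ft[1:2, 3:4]
  Sigma <- F12 %*% t(F11)
  Sigma <- (Sigma + t(Sigma)) / 2
  list(mean = as.numeric(F11 %*% origin), covariance = Sigma)
}

#' Gaussian solution of the Ornstein-Uhlenbeck process
#'
#' Expected counts per cell: bivariate Gaussian with moments from
#' \code{\link{ou_moments}}, midpoint rule (density at the cell center times
#' the cell measure).
#'
#' @inheritParams ou_moments
#' @param domain a \code{\link{simulation_domain}}.
#' @param count initial particle count.
#' @return N x N matrix of expected counts.
#' @export
ou_solution <- function(domain, relaxation, diffusivity, count, time,
                        origin = c(0, 0)) {
  if (time == 0) return(point_mass_counts(domain, origin, count))
  mom <- ou_moments(relaxation, diffusivity, time, origin)
  S <- mom$covariance
  Sinv <- solve(S)
  dS <- det(S)
  xs <- axis_coordinates(domain, 1) - mom$mean[1]
  ys <- axis_coordinates(domain, 2) - mom$mean[2]
  n <- domain$cells_per_dim
  X <- matrix(xs, n, n); Y <- matrix(ys, n, n, byrow = TRUE)
  q <- Sinv[1, 1] * X^2 + 2 * Sinv[1, 2] * X * Y + Sinv[2, 2] * Y^2
  dens <- exp(-q / 2) / (2 * pi * sqrt(dS))
  count * dens * domain$spacing^2
}

#' Closed-form moments of the mean-field non-linear model
#'
#' For \code{dx = -[nu x + lambda (x - m1)] dt + sqrt(2 D) dW} started as a
#' point mass at \code{x0}, the density stays Gaussian with first moment
#' \code{m1(t) = x0 exp(-nu t)} and variance
#' \code{D/(nu + lambda) (1 - exp(-2 (nu + lambda) t))}; asymptotically
#' \code{m1 -> 0} and the variance saturates at \code{D/(nu + lambda)}.
#'
#' @param nu linear relaxation rate.
#' @param lambda mean-field coupling rate.
#' @param diffusivity diffusivity D.
#' @param x0 initial position.
#' @param time elapsed time.
#' @return list with \code{m1}, \code{variance}, \code{m2} (second raw
#'   moment) and \code{asymptotic} (list with \code{m1}, \code{variance}).
#' @export
nonlinear_moments <- function(nu, lambda, diffusivity, x0, time) {
  m1 <- x0 * exp(-nu * time)
  v <- diffusivity / (nu + lambda) * (1 - exp(-2 * (nu + lambda) * time))
  list(m1 = m1, variance = v, m2 = v + m1^2,
       asymptotic = list(m1 = 0, variance = diffusivity / (nu + lambda)))
}

#' Analytic solution of the mean-field non-linear benchmark
#'
#' Expected counts per cell for the one-dimensional mean-field process
#' embedded along one lattice axis (the other axis immobile): Gaussian along
#' the active axis with moments from \code{\link{nonlinear_moments}},
#' integrated exactly over cells; all mass stays in the source slice of the
#' immobile axis.
#'
#' @inheritParams nonlinear_moments
#' @param domain a \code{\link{simulation_domain}}.
#' @param count initial particle count.
#' @param origin length-2 initial position (the inactive axis component
#'   selects the occupied slice).
#' @param axis active axis (1 or 2).
#' @return N x N matrix of expected counts.
#' @export
nonlinear_solution <- function(domain, nu, lambda, diffusivity, count, time,
                               origin, axis = 1) {
  if (time == 0) return(point_mass_counts(domain, origin, count))
  mom <- nonlinear_moments(nu, lambda, diffusivity, origin[axis], time)
  h <- domain$spacing
  ctr <- axis_coordinates(domain, axis)
  sd <- sqrt(mom$variance)
  mass <- stats::pnorm(ctr + h / 2, mom$m1, sd) -
    stats::pnorm(ctr - h / 2, mom$m1, sd)
  n <- domain$cells_per_dim
  other <- if (axis == 1) 2 else 1
  slice <- nearest_cell_index(origin, domain)[1, other]
  m <- matrix(0, n, n)
  if (axis == 1) m[, slice] <- count * mass else m[slice, ] <- count * mass
  m
}

#' Root-mean-square error between two lattices
#'
#' Square root of the mean over cells of the squared count difference.
#'
#' @param simulated,analytic numeric matrices of identical shape.
#' @return scalar RMSE.
#' @export
rmse <- function(simulated, analytic) {
  if (!all(dim(simulated) == dim(analytic)))
    stop("shape mismatch between simulated and analytic counts",
         call. = FALSE)
  sqrt(mean((simulated - analytic)^2))
}
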