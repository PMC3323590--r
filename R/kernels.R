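# One-dimensional transition kernels.
#
# All kernels describe the motion of a particle obeying the Ito SDE
#   dx = a dt + sqrt(2 D) dW
# inside one lattice cell of spacing h, where a is the drift (length/time)
# and D the diffusivity (length^2/time). The first-passage-time (FPT) kernel
# is exact in the first two moments of the exit time from the symmetric
# interval (-h, h) around the cell center; the Fokker-Planck (FPE) kernel is
# the classical centered-difference discretization and is first-order
# accurate in the time step.
#
# Throughout, `beta = a*h/(2*D)` is half the cell Peclet number. The direct
# closed forms suffer catastrophic cancellation in the exit-time variance as
# beta -> 0, so a three-term Taylor series takes over for |beta| < 0.02
# (both branches agree to ~1e-10 at the switchover).

.PECLET_SERIES_THRESHOLD <- 0.02

check_axis_fields <- function(drift, diffusivity, spacing) {
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("spacing must be a single positive number", call. = FALSE)
  if (any(!is.finite(drift)))
    stop("drift must be finite", call. = FALSE)
  if (any(is.na(diffusivity)) || any(diffusivity < 0))
    stop("diffusivity must be non-negative", call. = FALSE)
  if (any(drift == 0 & diffusivity == 0))
    stop("immobile species: drift and diffusivity are both zero", call. = FALSE)
  invisible(TRUE)
}

#' Splitting probabilities of the first-passage problem
#'
#' Probability that a particle started at a cell center first exits the
#' symmetric interval \code{(-spacing, spacing)} through the right
#' (\code{p_plus}) or left (\code{p_minus}) boundary. These are the
#' time-integrated (conditional) jump probabilities of the lattice walk and
#' always satisfy \code{p_minus + p_plus = 1}.
#'
#' @param drift drift coefficient (length/time); may be a vector.
#' @param diffusivity diffusivity (length^2/time), non-negative; recycled
#'   against \code{drift}.
#' @param spacing lattice spacing (length), a single positive number.
#' @return list with numeric components \code{p_minus} and \code{p_plus}.
#' @examples
#' fpt_splitting_probabilities(0, 1, 1)      # unbiased: 1/2, 1/2
#' fpt_splitting_probabilities(1, 1, 1)$p_plus  # logistic in the Peclet number
#' @export
fpt_splitting_probabilities <- function(drift, diffusivity, spacing) {
  check_axis_fields(drift, diffusivity, spacing)
  n <- max(length(drift), length(diffusivity))
  a <- rep_len(drift, n)
  D <- rep_len(diffusivity, n)
  pe <- a * spacing / D               # Inf with the sign of a when D = 0
  pe[a == 0] <- 0
  # each tail computed directly for full relative precision; the logistic
  # form is overflow-safe (exp(+large) -> Inf -> p -> 0)
  p_plus <- 1 / (1 + exp(-pe))
  p_minus <- 1 / (1 + exp(pe))
  list(p_minus = p_minus, p_plus = p_plus)
}

# Bracket tanh(b)^2 + tanh(b)/b - 1 with series switchover; vectorized.
.exit_bracket <- function(beta) {
  out <- numeric(length(beta))
  small <- abs(beta) < .PECLET_SERIES_THRESHOLD
  b2 <- beta[small]^2
  out[small] <- b2 * (2 / 3 - (8 / 15) * b2 + (34 / 105) * b2 * b2)
  bl <- beta[!small]
  th <- tanh(bl)
  out[!small] <- th * th + th / bl - 1
  out
}

#' First two moments of the cell exit time
#'
#' Mean and variance of the time at which a particle started at the cell
#' center first exits the symmetric interval \code{(-spacing, spacing)}.
#' For zero drift the mean is \code{spacing^2/(2*diffusivity)}; for vanishing
#' diffusivity with non-zero drift the ballistic limit
#' (mean \code{spacing/|drift|}, variance 0) is returned.
#'
#' @inheritParams fpt_splitting_probabilities
#' @return list with components \code{mean} and \code{variance}.
#' @export
fpt_exit_time_moments <- function(drift, diffusivity, spacing) {
  check_axis_fields(drift, diffusivity, spacing)
  n <- max(length(drift), length(diffusivity))
  a <- rep_len(drift, n)
  D <- rep_len(diffusivity, n)
  h <- spacing
  mean_t <- variance_t <- numeric(n)

  ballistic <- D == 0                       # a != 0 guaranteed by check
  mean_t[ballistic] <- h / abs(a[ballistic])
  variance_t[ballistic] <- 0

  zd <- !ballistic & a == 0
  mean_t[zd] <- h^2 / (2 * D[zd])
  variance_t[zd] <- h^4 / (6 * D[zd]^2)

  gen <- !ballistic & a != 0
  if (any(gen)) {
    ag <- a[gen]; Dg <- D[gen]
    beta <- ag * h / (2 * Dg)
    mean_t[gen] <- (h / ag) * tanh(beta)    # positive: signs cancel
    cc <- (h^2 / Dg)^2 / (4 * beta^2)
    variance_t[gen] <- cc * .exit_bracket(beta)
    # extreme Peclet: tanh saturates, bracket -> 1/beta, all finite; no guard
    huge <- is.infinite(beta)
    variance_t[gen][huge] <- 2 * h * Dg[huge] / abs(ag[huge])^3
  }
  list(mean = mean_t, variance = variance_t)
}

#' Canonical time step and rest probability of the discrete-time walk
#'
#' The fixed-step lattice walk that matches both the mean and the variance of
#' the continuous exit time lets the particle rest with probability
#' \code{rest = variance/mean^2} and uses the time step
#' \code{(1 - rest) * mean}. Plugging these into
#' \code{\link{rescaled_probabilities}} reproduces the FPT splitting
#' probabilities exactly.
#'
#' @inheritParams fpt_splitting_probabilities
#' @return list with components \code{timestep} and \code{rest}.
#' @export
canonical_step <- function(drift, diffusivity, spacing) {
  m <- fpt_exit_time_moments(drift, diffusivity, spacing)
  rest <- m$variance / m$mean^2
  list(timestep = (1 - rest) * m$mean, rest = rest)
}

#' Jump and rest probabilities for an arbitrary admissible time step
#'
#' Inverts the macroscopic moment identities of the lattice walk (effective
#' drift and diffusivity as functions of the conditional jump probabilities,
#' rest probability and time step) so that any time step not exceeding the
#' canonical one reproduces the input coefficients exactly:
#' \code{rest = 1 - dt*(2*D + a^2*dt)/h^2},
#' \code{p_plus/minus = 1/2 +- a*h / (2*(2*D + a^2*dt))}.
#'
#' @inheritParams fpt_splitting_probabilities
#' @param timestep global time step, \code{0 < timestep <= canonical}.
#' @return list with components \code{p_minus}, \code{p_plus} (conditional
#'   jump probabilities, summing to 1) and \code{rest}.
#' @export
rescaled_probabilities <- function(drift, diffusivity, spacing, timestep) {
  check_axis_fields(drift, diffusivity, spacing)
  if (any(!is.finite(timestep)) || any(timestep <= 0))
    stop("timestep must be positive and finite", call. = FALSE)
  n <- max(length(drift), length(diffusivity), length(timestep))
  a <- rep_len(drift, n)
  D <- rep_len(diffusivity, n)
  dt <- rep_len(timestep, n)
  h <- spacing
  denom <- 2 * D + a^2 * dt
  rest <- 1 - dt * denom / h^2
  p_plus <- 0.5 + a * h / (2 * denom)
  # a genuinely inadmissible step is a scheduling bug and must not be
  # clamped; rounding-level overshoot (the canonical step itself can land a
  # hair outside [0, 1] at high Peclet) is not
  tol <- 1e-9
  bad <- rest < -tol | p_plus > 1 + tol | p_plus < -tol
  if (any(bad))
    stop("timestep too large for cell (rest or jump probability out of range); ",
         "this indicates a scheduling bug", call. = FALSE)
  rest <- pmin(pmax(rest, 0), 1)
  p_plus <- pmin(pmax(p_plus, 0), 1)
  list(p_minus = 1 - p_plus, p_plus = p_plus, rest = rest)
}

#' Constant-coefficient Fokker-Planck transition probabilities
#'
#' Centered-difference discretization of the one-dimensional Fokker-Planck
#' equation with constant drift and diffusivity. The unconditional jump
#' probabilities are \code{D*dt/h^2 +- a*dt/(2*h)}; they are returned in the
#' conditional representation used throughout the package.
#'
#' @inheritParams rescaled_probabilities
#' @return list with components \code{p_minus}, \code{p_plus}, \code{rest}.
#' @export
fpe_probabilities <- function(drift, diffusivity, spacing, timestep) {
  check_axis_fields(drift, diffusivity, spacing)
  if (any(!is.finite(timestep)) || any(timestep <= 0))
    stop("timestep must be positive and finite", call. = FALSE)
  n <- max(length(drift), length(diffusivity), length(timestep))
  a <- rep_len(drift, n)
  D <- rep_len(diffusivity, n)
  dt <- rep_len(timestep, n)
  h <- spacing
  w_plus <- D * dt / h^2 + a * dt / (2 * h)
  w_minus <- D * dt / h^2 - a * dt / (2 * h)
  rest <- 1 - w_plus - w_minus
  if (any(w_plus < 0 | w_minus < 0 | rest < 0))
    stop("FPE kernel unstable for these parameters ",
         "(negative transition or rest probability)", call. = FALSE)
  jump <- w_plus + w_minus
  p_plus <- ifelse(jump > 0, w_plus / jump, 0.5)
  list(p_minus = 1 - p_plus, p_plus = p_plus, rest = rest)
}

#' Inhomogeneous Fokker-Planck transition probabilities
#'
#' Centered master-equation discretization consistent with the Ito
#' Fokker-Planck equation \code{dp/dt = -d(a p)/dx + d^2(D p)/dx^2} for
#' spatially varying coefficients. The discretization is non-local: the jump
#' probability towards a neighbor uses the interface diffusivity
#' \code{(D_center + D_neighbor)/2} and the Ito-corrected drift
#' \code{a - dD/dx} with the gradient taken by centered differences of the
#' neighboring cell-center values. When all three cells carry identical
#' fields the result reduces exactly to \code{\link{fpe_probabilities}}.
#'
#' @param left,center,right lists with numeric components \code{drift} and
#'   \code{diffusivity} holding the field values at the three cell centers
#'   (vectors of a common length). Boundary cells should carry ghost values
#'   chosen by the boundary policy (mirror for reflective, copy for outflow).
#' @inheritParams rescaled_probabilities
#' @return list with components \code{p_minus}, \code{p_plus}, \code{rest}.
#' @export
fpe_inhomogeneous_probabilities <- function(left, center, right,
                                            spacing, timestep) {
  check_axis_fields(center$drift, center$diffusivity, spacing)
  h <- spacing
  dt <- timestep
  b <- center$drift - (right$diffusivity - left$diffusivity) / (2 * h)
  Dp <- (center$diffusivity + right$diffusivity) / 2
  Dm <- (center$diffusivity + left$diffusivity) / 2
  w_plus <- Dp * dt / h^2 + b * dt / (2 * h)
  w_minus <- Dm * dt / h^2 - b * dt / (2 * h)
  rest <- 1 - w_plus - w_minus
  if (any(w_plus < 0 | w_minus < 0 | rest < 0))
    stop("FPE kernel unstable for these parameters ",
         "(negative transition or rest probability)", call. = FALSE)
  jump <- w_plus + w_minus
  p_plus <- ifelse(jump > 0, w_plus / jump, 0.5)
  list(p_minus = 1 - p_plus, p_plus = p_plus, rest = rest)
}

#' Macroscopic coefficients of a lattice walk
#'
#' Diagnostic inversion: given the conditional jump probabilities, the rest
#' probability, the time step and the spacing, return the effective drift and
#' diffusivity of the resulting continuous-time lattice random walk. Exact on
#' triples produced by \code{\link{rescaled_probabilities}}.
#'
#' @param p_minus,p_plus conditional jump probabilities (sum to 1).
#' @param rest rest probability in \code{[0, 1)}.
#' @param timestep time step of the walk.
#' @param spacing lattice spacing.
#' @return list with components \code{drift} and \code{diffusivity}.
#' @export
ctrw_effective_coefficients <- function(p_minus, p_plus, rest,
                                        timestep, spacing) {
  if (any(timestep <= 0) || spacing <= 0)
    stop("timestep and spacing must be positive", call. = FALSE)
  h <- spacing
  q <- (1 - rest) * (p_plus - p_minus)
  drift <- h * q / timestep
  diffusivity <- h^2 * (1 - rest) * (1 - q * (p_plus - p_minus)) /
    (2 * timestep)
  list(drift = drift, diffusivity = diffusivity)
}
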