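# Drift/diffusivity field models.
#
# A field model is an evaluator mapping (domain, state, time, species) to
# per-cell, per-axis drift and diffusivity matrices. Diffusivity matrices are
# diagonal (one value per axis per cell); off-diagonal diffusion tensors are
# out of contract. Models declare whether they depend on the lattice state
# or on time, so the propagator can evaluate constant fields once.

#' Construct a field model
#'
#' @param evaluator a function \code{(domain, state, time, species)}
#'   returning a list with components \code{drift_x}, \code{drift_y},
#'   \code{diff_x}, \code{diff_y}; each either a scalar or an N x N matrix.
#'   Evaluation must be free of side effects.
#' @param state_dependent does the field depend on the particle state?
#' @param time_dependent does the field depend explicitly on time?
#' @return an object of class \code{"field_model"}.
#' @export
field_model <- function(evaluator, state_dependent = FALSE,
                        time_dependent = FALSE) {
  stopifnot(is.function(evaluator))
  structure(list(evaluator = evaluator,
                 state_dependent = isTRUE(state_dependent),
                 time_dependent = isTRUE(time_dependent)),
            class = "field_model")
}

#' Evaluate a field model on the lattice
#'
#' Expands scalars to full matrices and validates shapes and positivity.
#'
#' @param field a \code{\link{field_model}}.
#' @param domain a \code{\link{simulation_domain}}.
#' @param state a \code{\link{lattice_state}}.
#' @param time evaluation time.
#' @param species species name the field applies to.
#' @return list of four N x N matrices: \code{drift_x}, \code{drift_y},
#'   \code{diff_x}, \code{diff_y}.
#' @export
eval_fields <- function(field, domain, state, time, species = "A") {
  f <- field$evaluator(domain, state, time, species)
  n <- domain$cells_per_dim
  expand <- function(v, what) {
    if (length(v) == 1L) v <- matrix(v, n, n)
    if (!is.matrix(v) || !all(dim(v) == c(n, n)))
      stop("field evaluator returned wrong shape for ", what, call. = FALSE)
    v
  }
  out <- list(drift_x = expand(f$drift_x, "drift_x"),
              drift_y = expand(f$drift_y, "drift_y"),
              diff_x = expand(f$diff_x, "diff_x"),
              diff_y = expand(f$diff_y, "diff_y"))
  for (nm in c("drift_x", "drift_y")) {
    bad <- !is.finite(out[[nm]])
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("non-finite %s for species '%s' at cell (%d, %d)",
                   nm, species, w[1], w[2]), call. = FALSE)
    }
  }
  for (nm in c("diff_x", "diff_y")) {
    bad <- !is.finite(out[[nm]]) | out[[nm]] < 0
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("invalid %s for species '%s' at cell (%d, %d)",
                   nm, species, w[1], w[2]), call. = FALSE)
    }
  }
  out
}

#' Homogeneous drift-diffusion field
#'
#' @param drift length-2 numeric, drift per axis.
#' @param diffusivity length-2 numeric, diffusivity per axis.
#' @return a \code{\link{field_model}}.
#' @export
homogeneous_field <- function(drift = c(0, 0), diffusivity = c(1, 1)) {
  drift <- rep_len(drift, 2); diffusivity <- rep_len(diffusivity, 2)
  field_model(function(domain, state, time, species)
    list(drift_x = drift[1], drift_y = drift[2],
         diff_x = diffusivity[1], diff_y = diffusivity[2]))
}

#' Geometric-Brownian-motion field
#'
#' Multiplicative-noise process per axis: drift \code{growth * x} and
#' diffusivity \code{volatility^2 * x^2 / 2} (noise amplitude
#' \code{volatility * x} in the \code{sqrt(2 D)} convention). The domain must
#' be shifted so that all cell coordinates are strictly positive, otherwise
#' the center cell has vanishing diffusivity.
#'
#' @param growth length-2 numeric, per-axis growth rate.
#' @param volatility length-2 numeric, per-axis noise amplitude.
#' @return a \code{\link{field_model}}.
#' @export
gbm_field <- function(growth, volatility) {
  growth <- rep_len(growth, 2); volatility <- rep_len(volatility, 2)
  field_model(function(domain, state, time, species) {
    xs <- axis_coordinates(domain, 1)
    ys <- axis_coordinates(domain, 2)
    if (any(xs <= 0) || any(ys <= 0))
      stop("GBM field requires strictly positive coordinates; ",
           "shift the domain origin", call. = FALSE)
    n <- domain$cells_per_dim
    X <- matrix(xs, n, n)            # varies along rows (axis 1)
    Y <- matrix(ys, n, n, byrow = TRUE)
    list(drift_x = growth[1] * X, drift_y = growth[2] * Y,
         diff_x = volatility[1]^2 * X^2 / 2,
         diff_y = volatility[2]^2 * Y^2 / 2)
  })
}

#' Ornstein-Uhlenbeck field
#'
#' Linear relaxation drift \code{-A \%*\% x} (the relaxation matrix \code{A}
#' need not be diagonal, which couples the axes and exercises dimensional
#' splitting) with constant diagonal diffusivity.
#'
#' @param relaxation 2 x 2 relaxation matrix.
#' @param diffusivity length-2 numeric, per-axis diffusivity.
#' @return a \code{\link{field_model}}.
#' @export
ou_field <- function(relaxation, diffusivity = c(1, 1)) {
  A <- matrix(as.numeric(relaxation), 2, 2)
  diffusivity <- rep_len(diffusivity, 2)
  field_model(function(domain, state, time, species) {
    xs <- axis_coordinates(domain, 1)
    ys <- axis_coordinates(domain, 2)
    n <- domain$cells_per_dim
    X <- matrix(xs, n, n)
    Y <- matrix(ys, n, n, byrow = TRUE)
    list(drift_x = -(A[1, 1] * X + A[1, 2] * Y),
         drift_y = -(A[2, 1] * X + A[2, 2] * Y),
         diff_x = diffusivity[1], diff_y = diffusivity[2])
  })
}

#' Count-weighted mean coordinate of the current state
#'
#' The empirical first moment of the particle distribution along one axis,
#' used as the mean-field input of the non-linear drift. Registered by the
#' non-linear field model so the drift always uses the current state; the
#' propagator re-evaluates state-dependent fields after every sweep.
#'
#' @param state a \code{\link{lattice_state}}.
#' @param domain a \code{\link{simulation_domain}}.
#' @param axis 1 (x) or 2 (y).
#' @param species species name.
#' @return the count-weighted mean coordinate (scalar).
#' @export
nonlinear_drift_hook <- function(state, domain, axis = 1, species = "A") {
  m <- state$counts[[species]]
  tot <- sum(m)
  if (tot == 0)
    stop("nonlinear drift undefined for empty state", call. = FALSE)
  coords <- axis_coordinates(domain, axis)
  per_slice <- if (axis == 1) rowSums(m) else colSums(m)
  sum(per_slice * coords) / tot
}

#' Mean-field non-linear relaxation field
#'
#' One-dimensional mean-field model along one lattice axis:
#' drift \code{-nu*x - lambda*(x - m1)} where \code{m1} is the count-weighted
#' empirical first moment of the current state, with constant diffusivity.
#' The other axis is immobile (zero drift and diffusivity), so the 1-D
#' process is embedded in the 2-D lattice.
#'
#' @param nu linear relaxation rate (1/time).
#' @param lambda mean-field coupling rate (1/time).
#' @param diffusivity diffusivity along the active axis.
#' @param axis active axis (1 or 2).
#' @return a \code{\link{field_model}} (state-dependent).
#' @export
nonlinear_field <- function(nu, lambda, diffusivity, axis = 1) {
  stopifnot(axis %in% c(1L, 2L))
  field_model(function(domain, state, time, species) {
    m1 <- nonlinear_drift_hook(state, domain, axis = axis, species = species)
    coords <- axis_coordinates(domain, axis)
    n <- domain$cells_per_dim
    C <- if (axis == 1) matrix(coords, n, n) else matrix(coords, n, n, byrow = TRUE)
    drift <- -nu * C - lambda * (C - m1)
    if (axis == 1)
      list(drift_x = drift, drift_y = 0, diff_x = diffusivity, diff_y = 0)
    else
      list(drift_x = 0, drift_y = drift, diff_x = 0, diff_y = diffusivity)
  }, state_dependent = TRUE)
}
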