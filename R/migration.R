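# Cell-migration application: neurons leaving a circular explant under
# contact inhibition of locomotion and, after a switch-on time, repulsion by
# the guidance protein Slit applied at one domain edge.
#
# The model couples a state-dependent scalar interaction field mu(x, t) to
# the transport kernel: the per-cell diffusivity is mu itself and the drift
# is its spatial gradient (centered differences), which in the macroscopic
# limit yields the minimal Keller-Segel model with vanishing chemotactic
# sensitivity (flux = grad(mu * n)). Contact inhibition divides the
# single-cell motility by (1 + density/saturation); Slit multiplies it by
# exp(-amplitude * S) with the steady exponential profile
# S = exp(-distance_from_source_edge / scale).

#' Default parameters of the cell-migration model
#'
#' Package-chosen synthetic defaults on a micron/hour scale representative
#' of neuron explant assays (the model structure follows the published
#' explant experiments; these magnitudes are this package's documented
#' choice, not transcribed measurements).
#'
#' @param motility single-cell motility (um^2/h).
#' @param saturation_density crowding saturation parameter (cells/um^2).
#' @param slit_amplitude dimensionless Slit coupling amplitude.
#' @param slit_scale Slit profile decay length (um).
#' @param slit_time Slit application time (h).
#' @param slit_edge domain edge carrying the Slit source.
#' @param explant_diameter explant diameter (um).
#' @param count number of neurons in the explant.
#' @param side_length domain side (um).
#' @param cells_per_dim lattice cells per dimension.
#' @param t_end total simulated time (h).
#' @return a named list of class \code{"migration_parameters"}.
#' @export
migration_parameters <- function(motility = 1000,
                                 saturation_density = 0.01,
                                 slit_amplitude = 3,
                                 slit_scale = 500,
                                 slit_time = 24,
                                 slit_edge = c("ymin", "ymax", "xmin", "xmax"),
                                 explant_diameter = 300,
                                 count = 1000,
                                 side_length = 2000,
                                 cells_per_dim = 64,
                                 t_end = 48) {
  slit_edge <- match.arg(slit_edge)
  stopifnot(motility > 0, saturation_density > 0, slit_scale > 0,
            explant_diameter > 0)
  structure(list(motility = motility,
                 saturation_density = saturation_density,
                 slit_amplitude = slit_amplitude,
                 slit_scale = slit_scale,
                 slit_time = slit_time,
                 slit_edge = slit_edge,
                 explant_diameter = explant_diameter,
                 count = count,
                 side_length = side_length,
                 cells_per_dim = cells_per_dim,
                 t_end = t_end),
            class = "migration_parameters")
}

# signed distance of each cell center from the Slit source edge, plus the
# outward unit direction (away from the source) as an axis/sign pair
slit_geometry <- function(domain, edge) {
  xs <- axis_coordinates(domain, 1)
  ys <- axis_coordinates(domain, 2)
  h <- domain$spacing
  switch(edge,
    ymin = list(axis = 2, sign = +1, dist = ys - (min(ys) - h / 2)),
    ymax = list(axis = 2, sign = -1, dist = (max(ys) + h / 2) - ys),
    xmin = list(axis = 1, sign = +1, dist = xs - (min(xs) - h / 2)),
    xmax = list(axis = 1, sign = -1, dist = (max(xs) + h / 2) - xs))
}

#' Evaluate the migration interaction field
#'
#' Computes the scalar interaction field per cell from the local neuron
#' density and the static Slit profile, then returns the per-cell, per-axis
#' drift (centered-difference gradient of the field, edge values replicated)
#' and diffusivity (the field itself).
#'
#' @param state a \code{\link{lattice_state}} holding the neuron counts.
#' @param domain a \code{\link{simulation_domain}}.
#' @param time current time; the Slit factor is active for
#'   \code{time >= slit_time}.
#' @param params a \code{\link{migration_parameters}} list.
#' @param species species name of the neurons.
#' @return list with \code{drift_x}, \code{drift_y}, \code{diff_x},
#'   \code{diff_y} and the scalar \code{interaction} matrix.
#' @export
migration_field <- function(state, domain, time, params, species = "neuron") {
  h <- domain$spacing
  n <- domain$cells_per_dim
  if (is.null(state$counts[[species]]))
    stop("state has no species '", species, "'", call. = FALSE)
  rho <- state$counts[[species]] / h^2
  mu <- params$motility / (1 + rho / params$saturation_density)
  if (time >= params$slit_time) {
    geo <- slit_geometry(domain, params$slit_edge)
    S <- exp(-geo$dist / params$slit_scale)
    Sm <- if (geo$axis == 2) matrix(S, n, n, byrow = TRUE) else matrix(S, n, n)
    mu <- mu * exp(-params$slit_amplitude * Sm)
  }
  # centered-difference gradient with edge replication
  gx <- (mu[c(2:n, n), ] - mu[c(1, 1:(n - 1)), ]) / (2 * h)
  gy <- (mu[, c(2:n, n)] - mu[, c(1, 1:(n - 1))]) / (2 * h)
  list(drift_x = gx, drift_y = gy, diff_x = mu, diff_y = mu,
       interaction = mu)
}

#' Field model wrapper for the migration application
#'
#' @inheritParams migration_field
#' @return a state- and time-dependent \code{\link{field_model}}.
#' @export
migration_field_model <- function(params, species = "neuron") {
  field_model(function(domain, state, time, sp) {
    f <- migration_field(state, domain, time, params, species = species)
    f[c("drift_x", "drift_y", "diff_x", "diff_y")]
  }, state_dependent = TRUE, time_dependent = TRUE)
}

#' Asymmetry of the neuron distribution relative to the Slit source
#'
#' Count-weighted mean of the signed distance from the explant center along
#' the axis perpendicular to the Slit edge, with positive values pointing
#' away from the source. Mirror-symmetric distributions score 0; a
#' distribution skewed away from the source scores positive.
#'
#' @param state a \code{\link{lattice_state}}.
#' @param domain a \code{\link{simulation_domain}}.
#' @param source_edge domain edge carrying the Slit source.
#' @param center explant center coordinates.
#' @param species species name.
#' @return the asymmetry statistic (length units).
#' @export
migration_asymmetry <- function(state, domain,
                                source_edge = c("ymin", "ymax", "xmin", "xmax"),
                                center = c(0, 0), species = "neuron") {
  source_edge <- match.arg(source_edge)
  m <- state$counts[[species]]
  tot <- sum(m)
  if (tot == 0) stop("asymmetry undefined for empty state", call. = FALSE)
  geo <- slit_geometry(domain, source_edge)
  coords <- axis_coordinates(domain, geo$axis)
  per_slice <- if (geo$axis == 1) rowSums(m) else colSums(m)
  geo$sign * (sum(per_slice * coords) / tot - center[geo$axis])
}
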