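# Runnable benchmark configurations.
#
# Four analytically solvable transport problems (homogeneous biased
# diffusion, geometric Brownian motion, Ornstein-Uhlenbeck, mean-field
# non-linear relaxation) plus the cell-migration application. Sizes follow
# the published setups where stated (point source at the center cell,
# outflow boundaries, 100 runs); magnitudes that are not printed anywhere
# (particle counts, domain sides, coefficient values, stop times) are the
# package's documented defaults, with stop times chosen so that the analytic
# mass outside the domain stays below 1e-6.

benchmark_defaults <- function(problem) {
  switch(problem,
    homogeneous = list(
      side_length = 40, boundary = "outflow", count = 1e4, t_end = 2,
      origin = c(0, 0), origin_shift = c(0, 0),
      snapshot_times = 2,
      params = list(drift = c(2, 2), diffusivity = c(1, 1))),
    gbm = list(
      side_length = 40, boundary = "outflow", count = 1e4, t_end = 1,
      origin = c(40, 40), origin_shift = c(40, 40),  # shift by the width
      snapshot_times = 1,
      params = list(growth = c(0.05, 0.05), volatility = c(0.07, 0.07))),
    ou = list(
      side_length = 12, boundary = "outflow", count = 1e4, t_end = 1,
      origin = c(0, 0), origin_shift = c(0, 0),
      snapshot_times = c(0.25, 0.5, 1),
      params = list(rho = 1, coupling = 0.5, diffusivity = c(1, 1))),
    nonlinear = list(
      side_length = 7, boundary = "outflow", count = 1e4, t_end = 5,
      origin = c(1.5, 0), origin_shift = c(0, 0),
      snapshot_times = c(0.5, 1, 2, 3.5, 5),
      params = list(nu = 1, lambda = 1, diffusivity = 0.5, axis = 1)),
    migration = {
      mp <- migration_parameters()
      list(side_length = mp$side_length, boundary = "outflow",
           count = mp$count, t_end = mp$t_end,
           origin = c(0, 0), origin_shift = c(0, 0),
           snapshot_times = c(mp$slit_time, mp$t_end),
           params = mp)
    },
    stop("unknown problem '", problem, "'", call. = FALSE))
}

#' Assemble a benchmark configuration
#'
#' Fills in the documented defaults for one of the named benchmark problems
#' and applies any overrides. The resulting configuration is a plain list
#' and can be serialized/parsed with \code{\link{serialize_config}} /
#' \code{\link{parse_config}}.
#'
#' @param problem one of \code{"homogeneous"}, \code{"gbm"}, \code{"ou"},
#'   \code{"nonlinear"}, \code{"migration"}.
#' @param cells_per_dim lattice cells per dimension.
#' @param kernel \code{"fpt"} or \code{"fpe"}.
#' @param runs ensemble size.
#' @param seed base RNG seed (required; all randomness derives from it).
#' @param ... overrides for any top-level field or \code{params} entry.
#' @return a configuration list of class \code{"run_config"}.
#' @export
benchmark_config <- function(problem, cells_per_dim = 64,
                             kernel = c("fpt", "fpe"), runs = 100, seed,
                             ...) {
  if (length(kernel) > 1) kernel <- kernel[1]
  if (!kernel %in% c("fpt", "fpe"))
    stop("invalid value for field 'kernel': ", kernel, call. = FALSE)
  if (missing(seed)) stop("seed is required (no silent nondeterminism)",
                          call. = FALSE)
  cfg <- benchmark_defaults(problem)
  cfg$problem <- problem
  cfg$cells_per_dim <- as.integer(cells_per_dim)
  cfg$kernel <- kernel
  cfg$runs <- as.integer(runs)
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(cfg$params)) cfg$params[[nm]] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  validate_config(cfg)
}

# problem-specific assembly: domain, initial state, field model, species
build_problem <- function(cfg) {
  dom <- simulation_domain(cfg$side_length, cfg$cells_per_dim,
                           boundary = cfg$boundary,
                           origin_shift = cfg$origin_shift)
  p <- cfg$params
  if (cfg$problem == "migration") {
    state <- place_initial_condition(dom, "disc", count = cfg$count,
                                     center = cfg$origin,
                                     radius = p$explant_diameter / 2,
                                     species = "neuron")
    fields <- migration_field_model(p)
    analytic <- NULL
  } else {
    state <- place_initial_condition(dom, "point", count = cfg$count,
                                     center = cfg$origin)
    # snap the analytic origin to the occupied cell center
    origin_eff <- as.numeric(
      cell_center_coordinates(nearest_cell_index(cfg$origin, dom), dom))
    fields <- switch(cfg$problem,
      homogeneous = homogeneous_field(p$drift, p$diffusivity),
      gbm = gbm_field(p$growth, p$volatility),
      ou = ou_field(ou_relaxation_matrix(p), p$diffusivity),
      nonlinear = nonlinear_field(p$nu, p$lambda, p$diffusivity,
                                  axis = p$axis))
    analytic <- switch(cfg$problem,
      homogeneous = function(time) gaussian_solution(
        dom, p$drift, p$diffusivity, cfg$count, time, origin_eff),
      gbm = function(time) gbm_solution(
        dom, p$growth, p$volatility, cfg$count, time, origin_eff),
      ou = function(time) ou_solution(
        dom, ou_relaxation_matrix(p), p$diffusivity, cfg$count, time,
        origin_eff),
      nonlinear = function(time) nonlinear_solution(
        dom, p$nu, p$lambda, p$diffusivity, cfg$count, time, origin_eff,
        axis = p$axis))
  }
  list(domain = dom, state = state, fields = fields, analytic = analytic,
       species = names(state$counts))
}

ou_relaxation_matrix <- function(p) {
  p$rho * matrix(c(1, p$coupling, p$coupling, 1), 2, 2)
}

# headline sweep parameter for the report table
benchmark_parameter <- function(cfg) {
  switch(cfg$problem,
    homogeneous = cfg$params$drift[1],
    gbm = cfg$params$growth[1],
    ou = cfg$params$rho,
    nonlinear = cfg$params$diffusivity,
    migration = cfg$params$slit_amplitude)
}

#' Run a benchmark configuration
#'
#' Executes the ensemble, scores the ensemble-mean lattice against the
#' analytic solution at every snapshot time (root-mean-square error per
#' cell, with a jackknife-over-runs standard error) and optionally writes
#' snapshots, the report table and a manifest to \code{out_dir}.
#'
#' For the migration problem, which has no closed-form solution, the report
#' rows carry the distribution asymmetry statistic (and its standard error
#' across runs) instead of an RMSE.
#'
#' @param cfg a configuration from \code{\link{benchmark_config}} or
#'   \code{\link{parse_config}}.
#' @param out_dir optional output directory.
#' @param keep_runs if \code{TRUE}, attach each run's snapshots to the
#'   result (needed for per-run statistics).
#' @return list with \code{report} (data frame), \code{mean} (per-snapshot
#'   ensemble-mean matrices), \code{analytic} (per-snapshot reference
#'   matrices or \code{NULL}), \code{domain}, \code{config} and optionally
#'   \code{per_run}.
#' @export
run_benchmark <- function(cfg, out_dir = NULL, keep_runs = FALSE) {
  cfg <- validate_config(cfg)
  pb <- build_problem(cfg)
  network <- if (!is.null(cfg$reactions))
    reaction_network(cfg$reactions, species = pb$species) else NULL
  ens <- run_ensemble(pb$state, pb$domain, pb$fields, cfg$t_end,
                      runs = cfg$runs, base_seed = cfg$seed,
                      kernel = cfg$kernel, network = network,
                      snapshot_times = cfg$snapshot_times,
                      keep_runs = TRUE)
  sp <- pb$species[1]
  times <- ens$times
  tnames <- names(ens$mean)
  rows <- list()
  analytic_list <- NULL
  if (!is.null(pb$analytic)) {
    analytic_list <- lapply(times, pb$analytic)
    names(analytic_list) <- tnames
    for (k in seq_along(times)) {
      ref <- analytic_list[[k]]
      per_run_mats <- lapply(ens$per_run, function(r)
        r[[tnames[k]]]$counts[[sp]])
      err <- rmse(ens$mean[[k]][[sp]], ref)
      # jackknife over runs
      R <- cfg$runs
      se <- NA_real_
      if (R > 1) {
        tot <- Reduce(`+`, per_run_mats)
        loo <- vapply(per_run_mats, function(m)
          rmse((tot - m) / (R - 1), ref), numeric(1))
        se <- sqrt((R - 1) / R * sum((loo - mean(loo))^2))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        problem = cfg$problem, kernel = cfg$kernel,
        cells_per_dim = cfg$cells_per_dim,
        parameter = benchmark_parameter(cfg), runs = cfg$runs,
        time = times[k], rmse = err, rmse_stderr = se,
        boundary_mass = 1 - sum(ref) / cfg$count)
    }
  } else {
    for (k in seq_along(times)) {
      stats_r <- vapply(ens$per_run, function(r) {
        st <- r[[tnames[k]]]
        migration_asymmetry(st, pb$domain,
                            source_edge = cfg$params$slit_edge,
                            center = cfg$origin, species = sp)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        problem = cfg$problem, kernel = cfg$kernel,
        cells_per_dim = cfg$cells_per_dim,
        parameter = benchmark_parameter(cfg), runs = cfg$runs,
        time = times[k], asymmetry = mean(stats_r),
        asymmetry_stderr = stats::sd(stats_r) / sqrt(length(stats_r)))
    }
  }
  report <- do.call(rbind, rows)
  out <- list(report = report, mean = ens$mean, analytic = analytic_list,
              domain = pb$domain, config = cfg)
  if (keep_runs) out$per_run <- ens$per_run
  if (!is.null(out_dir)) write_benchmark_outputs(out, out_dir)
  out
}

#' Weighted moments of a lattice distribution
#'
#' Count-weighted mean vector and covariance matrix over cell centers.
#'
#' @param counts N x N count (or expected-count) matrix.
#' @param domain a \code{\link{simulation_domain}}.
#' @return list with \code{mean}, \code{covariance} and \code{total}.
#' @export
state_moments <- function(counts, domain) {
  tot <- sum(counts)
  if (tot <= 0) stop("moments undefined for empty lattice", call. = FALSE)
  xs <- axis_coordinates(domain, 1)
  ys <- axis_coordinates(domain, 2)
  wx <- rowSums(counts); wy <- colSums(counts)
  mx <- sum(wx * xs) / tot
  my <- sum(wy * ys) / tot
  vxx <- sum(wx * (xs - mx)^2) / tot
  vyy <- sum(wy * (ys - my)^2) / tot
  n <- domain$cells_per_dim
  X <- matrix(xs - mx, n, n); Y <- matrix(ys - my, n, n, byrow = TRUE)
  vxy <- sum(counts * X * Y) / tot
  list(mean = c(mx, my),
       covariance = matrix(c(vxx, vxy, vxy, vyy), 2, 2),
       total = tot)
}

#' Weighted quantiles of a lattice distribution along one axis
#'
#' Linear interpolation of the cumulative marginal over cell centers; works
#' for integer counts and for expected (fractional) counts, so empirical and
#' analytic lattices are summarized identically.
#'
#' @param counts N x N count matrix.
#' @param domain a \code{\link{simulation_domain}}.
#' @param axis 1 (x) or 2 (y).
#' @param probs quantile levels.
#' @return numeric vector of quantiles.
#' @export
state_quantiles <- function(counts, domain, axis, probs = c(0.1, 0.5, 0.9)) {
  w <- if (axis == 1) rowSums(counts) else colSums(counts)
  coords <- axis_coordinates(domain, axis)
  tot <- sum(w)
  if (tot <= 0) stop("quantiles undefined for empty lattice", call. = FALSE)
  cum <- cumsum(w) / tot
  vapply(probs, function(p) {
    i <- which(cum >= p)[1]
    if (i == 1L) return(coords[1])
    c0 <- cum[i - 1L]
    coords[i - 1L] + (coords[i] - coords[i - 1L]) * (p - c0) / (cum[i] - c0)
  }, numeric(1))
}
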