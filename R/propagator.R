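# Time propagation by dimensional splitting.
#
# Each (species, axis) pair owns an alarm on a global event timeline. At each
# event the corresponding one-dimensional sweep redistributes every cell's
# particles to (left, stay, right) with the cell's transition probabilities;
# afterwards, if the field is state- or time-dependent (or reactions are
# active), the field is re-evaluated and the pair's time step recomputed
# before rescheduling. Inhomogeneous fields use the global-minimum canonical
# time step over all mobile cells, with probabilities rescaled per cell.
# When alarms coincide, the x sweep executes before the y sweep (and species
# in their declaration order).

axis_slot <- function(f, axis, what) f[[paste0(what, "_", c("x", "y")[axis])]]

# snapshot list keys: element-wise, so scalar and vector formatting agree
time_key <- function(t) vapply(t, function(x) format(x, digits = 15),
                               character(1))

#' Global minimum canonical time step for one species and axis
#'
#' Evaluates the field, computes the canonical time step in every mobile
#' cell (cells with zero drift and zero diffusivity are immobile and
#' excluded) and returns the minimum. Returns \code{Inf} when the species is
#' immobile on this axis, in which case it is never scheduled.
#'
#' @param field a \code{\link{field_model}}.
#' @param domain a \code{\link{simulation_domain}}.
#' @param state a \code{\link{lattice_state}}.
#' @param axis 1 (x) or 2 (y).
#' @param species species name.
#' @param kernel transition kernel; both kernels are scheduled with the
#'   canonical first-passage step.
#' @return the global minimum time step (possibly \code{Inf}).
#' @export
global_min_timestep <- function(field, domain, state, axis,
                                species = "A", kernel = c("fpt", "fpe")) {
  kernel <- match.arg(kernel)
  f <- eval_fields(field, domain, state, state$time, species)
  a <- axis_slot(f, axis, "drift")
  D <- axis_slot(f, axis, "diff")
  mobile <- !(a == 0 & D == 0)
  if (!any(mobile)) return(Inf)
  cs <- canonical_step(a[mobile], D[mobile], domain$spacing)
  min(cs$timestep)
}

# Build the per-cell transition plan for one (species, axis) from an already
# evaluated field. Returns NULL for an immobile axis.
build_sweep_plan <- function(fe, axis, domain, kernel) {
  a <- axis_slot(fe, axis, "drift")
  D <- axis_slot(fe, axis, "diff")
  n <- domain$cells_per_dim
  mobile <- !(a == 0 & D == 0)
  if (!any(mobile)) return(NULL)
  h <- domain$spacing
  cs <- canonical_step(a[mobile], D[mobile], h)
  dt <- min(cs$timestep)
  plan <- list(axis = axis, timestep = dt, mobile = mobile,
               drift = a, diff = D)
  plan$triple <- plan_triple(plan, domain, kernel, dt)
  plan$kernel <- kernel
  plan
}

# Transition triple (full matrices; immobile cells rest = 1) for a given
# actual time step (<= scheduled step; smaller for truncated sweeps).
#
# A truncated step can fall below the exact-moment admissibility bound
# dt >= (|a|h - 2D)/a^2 in drift-dominated cells (Peclet > 2); such cells
# use the upwind closure (all jump mass on the drift side), which keeps the
# drift exact at a bounded, one-off variance excess. Scheduled full steps
# never take this branch.
plan_triple <- function(plan, domain, kernel, dt, truncated = FALSE) {
  n <- domain$cells_per_dim
  h <- domain$spacing
  mobile <- plan$mobile
  p_plus <- matrix(0.5, n, n)
  rest <- matrix(1, n, n)
  if (kernel == "fpt") {
    a <- plan$drift[mobile]
    D <- plan$diff[mobile]
    if (truncated) {
      dt_lo <- pmax(0, (abs(a) * h - 2 * D) / a^2)
      dt_lo[a == 0] <- 0
      ok <- dt >= dt_lo
      pp <- rep(0.5, length(a)); rr <- rep(1, length(a))
      if (any(ok)) {
        tr_ok <- rescaled_probabilities(a[ok], D[ok], h, dt)
        pp[ok] <- tr_ok$p_plus; rr[ok] <- tr_ok$rest
      }
      if (any(!ok)) {
        pp[!ok] <- ifelse(a[!ok] > 0, 1, 0)
        rr[!ok] <- 1 - abs(a[!ok]) * dt / h
      }
      tr <- list(p_plus = pp, rest = rr)
    } else {
      tr <- rescaled_probabilities(a, D, h, dt)
    }
  } else {
    shift_mats <- neighbor_fields(plan$drift, plan$diff, plan$axis, domain)
    tr <- fpe_inhomogeneous_probabilities(
      left = list(drift = shift_mats$a_left[mobile],
                  diffusivity = shift_mats$D_left[mobile]),
      center = list(drift = plan$drift[mobile],
                    diffusivity = plan$diff[mobile]),
      right = list(drift = shift_mats$a_right[mobile],
                   diffusivity = shift_mats$D_right[mobile]),
      spacing = h, timestep = dt)
  }
  p_plus[mobile] <- tr$p_plus
  rest[mobile] <- tr$rest
  list(p_plus = p_plus, rest = rest)
}

# Neighbor field values along an axis with ghost cells by boundary policy:
# periodic wraps; outflow and reflective replicate the edge value (copy and
# zero-flux mirror coincide for the immediate ghost neighbor).
neighbor_fields <- function(a, D, axis, domain) {
  n <- domain$cells_per_dim
  shift <- function(m, dir) {
    # dir +1: value of neighbor at +axis; dir -1: neighbor at -axis
    if (axis == 1) {
      out <- if (dir > 0) m[c(2:n, n), , drop = FALSE] else m[c(1, 1:(n - 1)), , drop = FALSE]
      if (domain$boundary == "periodic") {
        out <- if (dir > 0) m[c(2:n, 1), , drop = FALSE] else m[c(n, 1:(n - 1)), , drop = FALSE]
      }
    } else {
      out <- if (dir > 0) m[, c(2:n, n), drop = FALSE] else m[, c(1, 1:(n - 1)), drop = FALSE]
      if (domain$boundary == "periodic") {
        out <- if (dir > 0) m[, c(2:n, 1), drop = FALSE] else m[, c(n, 1:(n - 1)), drop = FALSE]
      }
    }
    out
  }
  list(a_right = shift(a, 1), a_left = shift(a, -1),
       D_right = shift(D, 1), D_left = shift(D, -1))
}

#' Execute one dimensional-splitting sweep
#'
#' Partitions the particles of every cell into (stay, left, right) by
#' sampling the trinomial law with the cell's unconditional probabilities,
#' then moves the jumpers to their destination cells under the domain's
#' boundary policy. All destinations are computed from the pre-sweep state.
#'
#' @param counts an N x N count matrix (single species).
#' @param triple list with N x N matrices \code{p_plus} (conditional) and
#'   \code{rest}.
#' @param axis 1 (x, rows) or 2 (y, columns).
#' @param domain a \code{\link{simulation_domain}}.
#' @return the updated count matrix.
#' @export
sweep_axis <- function(counts, triple, axis, domain) {
  n <- domain$cells_per_dim
  occ <- which(counts > 0)
  if (length(occ) == 0L) return(counts)
  nv <- counts[occ]
  stay <- stats::rbinom(length(occ), nv, triple$rest[occ])
  movers <- nv - stay
  right <- stats::rbinom(length(occ), movers, triple$p_plus[occ])
  left <- movers - right

  new <- matrix(0, n, n)
  new[occ] <- stay

  i <- ((occ - 1L) %% n) + 1L            # row (x) index
  j <- ((occ - 1L) %/% n) + 1L           # column (y) index
  pos <- if (axis == 1) i else j
  stride <- if (axis == 1) 1L else n

  deposit <- function(amount, dir) {
    keep <- amount > 0
    if (!any(keep)) return(invisible())
    src <- occ[keep]; amt <- amount[keep]; p <- pos[keep]
    inward <- if (dir > 0) p < n else p > 1
    tgt <- src[inward] + dir * stride
    new[tgt] <<- new[tgt] + amt[inward]
    edge_amt <- amt[!inward]
    if (length(edge_amt)) {
      edge_src <- src[!inward]
      switch(domain$boundary,
        outflow = invisible(),                       # removed
        reflective = { new[edge_src] <<- new[edge_src] + edge_amt },
        periodic = {
          tgt <- edge_src - dir * stride * (n - 1L)
          new[tgt] <<- new[tgt] + edge_amt
        })
    }
    invisible()
  }
  deposit(right, +1L)
  deposit(left, -1L)
  new
}

#' Advance a lattice state in time
#'
#' Runs the dimensional-splitting event loop until \code{t_end}: repeatedly
#' executes the (species, axis) sweep with the earliest alarm, re-evaluating
#' dynamic fields and recomputing that pair's global-minimum time step before
#' rescheduling. Optional per-subvolume chemistry runs between consecutive
#' diffusion events (operator splitting). Snapshot times are honored exactly:
#' the final step before a snapshot is truncated, with probabilities rescaled
#' for the shorter interval.
#'
#' @param state a \code{\link{lattice_state}}.
#' @param domain a \code{\link{simulation_domain}}.
#' @param fields a \code{\link{field_model}} (applied to every species) or a
#'   named list of field models, one per species.
#' @param t_end end time (>= current clock).
#' @param kernel \code{"fpt"} (first-passage-time, default) or \code{"fpe"}
#'   (Fokker-Planck discretization).
#' @param network optional \code{\link{reaction_network}}.
#' @param snapshot_times numeric vector of times at which to record the
#'   state.
#' @param hooks optional list of functions \code{(state, info)} invoked after
#'   each sweep; \code{info} has components \code{time}, \code{species},
#'   \code{axis}, \code{timestep}.
#' @param event_log if \code{TRUE}, return a data frame of executed events.
#' @return a list with components \code{state} (final
#'   \code{\link{lattice_state}}), \code{snapshots} (list of states, named by
#'   time) and \code{events} (data frame or \code{NULL}).
#' @export
advance <- function(state, domain, fields, t_end,
                    kernel = c("fpt", "fpe"), network = NULL,
                    snapshot_times = numeric(0), hooks = NULL,
                    event_log = FALSE) {
  kernel <- match.arg(kernel)
  if (t_end < state$time) stop("t_end must be >= current time", call. = FALSE)
  species <- names(state$counts)
  if (inherits(fields, "field_model"))
    fields <- stats::setNames(rep(list(fields), length(species)), species)
  if (!all(species %in% names(fields)))
    stop("missing field model for species: ",
         paste(setdiff(species, names(fields)), collapse = ", "),
         call. = FALSE)
  snapshot_times <- sort(unique(snapshot_times))
  if (length(snapshot_times) && any(snapshot_times > t_end))
    stop("snapshot times must not exceed t_end", call. = FALSE)

  dynamic <- vapply(fields[species], function(f)
    f$state_dependent || f$time_dependent, logical(1)) | !is.null(network)

  # per (species, axis) scheduling record
  plans <- list()
  last <- alarm <- matrix(Inf, nrow = length(species), ncol = 2,
                          dimnames = list(species, c("x", "y")))
  reeval <- function(s) eval_fields(fields[[s]], domain, state, state$time, s)
  fe_cache <- stats::setNames(lapply(species, reeval), species)
  for (s in species) for (d in 1:2) {
    plans[[s]][d] <- list(build_sweep_plan(fe_cache[[s]], d, domain, kernel))
    last[s, d] <- state$time
    alarm[s, d] <- if (is.null(plans[[s]][[d]])) Inf else
      state$time + plans[[s]][[d]]$timestep
  }

  events <- if (event_log) list() else NULL
  snapshots <- list()

  run_chemistry <- function(interval) {
    if (!is.null(network) && interval > 0)
      state <<- react_between_events(state, network, interval, domain)
  }

  do_sweep <- function(s, d, t_sweep, dt_actual) {
    plan <- plans[[s]][[d]]
    triple <- if (abs(dt_actual - plan$timestep) < 1e-12 * plan$timestep)
      plan$triple else plan_triple(plan, domain, kernel, dt_actual,
                                   truncated = TRUE)
    state$counts[[s]] <<- sweep_axis(state$counts[[s]], triple, d, domain)
    state$time <<- t_sweep
    last[s, d] <<- t_sweep
    if (dynamic[[s]]) {
      fe_cache[[s]] <<- reeval(s)
      plans[[s]][d] <<- list(build_sweep_plan(fe_cache[[s]], d, domain,
                                              kernel))
    }
    alarm[s, d] <<- if (is.null(plans[[s]][[d]])) Inf else
      t_sweep + plans[[s]][[d]]$timestep
    if (event_log)
      events[[length(events) + 1L]] <<- data.frame(
        clock = t_sweep, species = s, axis = c("x", "y")[d],
        timestep = dt_actual)
    if (!is.null(hooks))
      for (hk in hooks)
        hk(state, list(time = t_sweep, species = s, axis = d,
                       timestep = dt_actual))
    invisible()
  }

  targets <- unique(c(snapshot_times, t_end))
  for (tt in targets) {
    repeat {
      t_next <- min(alarm)
      if (t_next > tt) break
      # earliest alarm; ties broken species-order first, x before y
      cand <- which(alarm == t_next, arr.ind = TRUE)
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      s <- species[cand[1, 1]]; d <- cand[1, 2]
      run_chemistry(t_next - state$time)
      do_sweep(s, d, t_next, plans[[s]][[d]]$timestep)
    }
    # truncate to hit the target exactly
    run_chemistry(tt - state$time)
    for (s in species) for (d in 1:2) {
      if (!is.null(plans[[s]][[d]]) && last[s, d] < tt)
        do_sweep(s, d, tt, tt - last[s, d])
    }
    state$time <- tt
    if (tt %in% snapshot_times)
      snapshots[[time_key(tt)]] <- state
  }
  list(state = state,
       snapshots = snapshots,
       events = if (event_log) do.call(rbind, events) else NULL)
}

#' Deterministic child seed for an ensemble run
#'
#' Mixes the base seed and run index with a fixed linear-congruential rule so
#' ensembles are reproducible run-by-run under single-threaded execution.
#'
#' @param base_seed integer base seed.
#' @param run run index (1-based).
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @export
child_seed <- function(base_seed, run) {
  m <- 2147483563
  as.integer((((base_seed %% m) * 40014 + run * 40692) %% m) + 1)
}

#' Run an ensemble of simulations
#'
#' Repeats \code{\link{advance}} from the same initial state with
#' deterministically derived child seeds and averages the per-cell counts at
#' each snapshot time.
#'
#' @inheritParams advance
#' @param runs number of runs (>= 1).
#' @param base_seed integer base seed; run \code{r} uses
#'   \code{\link{child_seed}(base_seed, r)}.
#' @param keep_runs if \code{TRUE}, also return each run's snapshots.
#' @return a list with components \code{mean} (list indexed by snapshot time,
#'   each a named list of per-species mean count matrices), \code{times},
#'   \code{runs}, and optionally \code{per_run}.
#' @export
run_ensemble <- function(state, domain, fields, t_end, runs, base_seed,
                         kernel = c("fpt", "fpe"), network = NULL,
                         snapshot_times = t_end, keep_runs = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(runs >= 1)
  snapshot_times <- sort(unique(snapshot_times))
  species <- names(state$counts)
  acc <- lapply(snapshot_times, function(tt)
    stats::setNames(lapply(species, function(s)
      matrix(0, domain$cells_per_dim, domain$cells_per_dim)), species))
  names(acc) <- time_key(snapshot_times)
  per_run <- if (keep_runs) vector("list", runs) else NULL
  for (r in seq_len(runs)) {
    set.seed(child_seed(base_seed, r))
    res <- advance(state, domain, fields, t_end, kernel = kernel,
                   network = network, snapshot_times = snapshot_times)
    for (tn in names(acc)) {
      if (is.null(res$snapshots[[tn]]))
        stop("internal error: snapshot '", tn, "' not recorded", call. = FALSE)
      for (s in species)
        acc[[tn]][[s]] <- acc[[tn]][[s]] + res$snapshots[[tn]]$counts[[s]]
    }
    if (keep_runs) per_run[[r]] <- res$snapshots
  }
  for (tn in names(acc)) for (s in species)
    acc[[tn]][[s]] <- acc[[tn]][[s]] / runs
  out <- list(mean = acc, times = snapshot_times, runs = runs)
  if (keep_runs) out$per_run <- per_run
  out
}
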