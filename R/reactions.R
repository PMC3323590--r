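# Per-subvolume stochastic chemical kinetics.
#
# Between consecutive diffusion events, every subvolume evolves
# independently under the Gillespie direct method (Lie operator splitting:
# chemistry over the full inter-event interval, then transport). Mass-action
# propensities use the standard compartment convention in two dimensions:
# bimolecular rate constants are scaled by the subvolume measure h^2.

#' Construct a reaction network
#'
#' Reactions are given as strings \code{"reactants -> products, rate"}, e.g.
#' \code{"A -> 0, 0.3"}, \code{"A + B -> C, 1e-3"}, \code{"0 -> A, 5"}.
#' Reactant order at most 2 (at most two reactant molecules).
#'
#' @param reactions character vector of reaction strings.
#' @param species optional character vector fixing the species universe;
#'   defaults to every species mentioned.
#' @return an object of class \code{"reaction_network"} with a species list,
#'   reactant/product stoichiometry matrices (species x reactions) and rate
#'   constants.
#' @examples
#' reaction_network(c("A -> 0, 0.5", "A + A -> B, 1e-2"))
#' @export
reaction_network <- function(reactions, species = NULL) {
  if (length(reactions) == 0L) {
    sp <- species %||% character(0)
    return(structure(list(species = sp,
                          reactants = matrix(0, length(sp), 0,
                                             dimnames = list(sp, NULL)),
                          products = matrix(0, length(sp), 0,
                                            dimnames = list(sp, NULL)),
                          rates = numeric(0),
                          labels = character(0)),
                     class = "reaction_network"))
  }
  parse_side <- function(txt) {
    txt <- trimws(txt)
    if (txt %in% c("0", "")) return(character(0))
    parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    unlist(lapply(parts, function(p) {
      m <- regmatches(p, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_]*)$", p))[[1]]
      if (length(m) == 0) stop("cannot parse species term '", p, "'",
                               call. = FALSE)
      k <- if (m[2] == "") 1L else as.integer(m[2])
      rep(m[3], k)
    }))
  }
  parsed <- lapply(reactions, function(r) {
    main <- strsplit(r, ",")[[1]]
    if (length(main) != 2) stop("reaction must be 'lhs -> rhs, rate': ", r,
                                call. = FALSE)
    rate <- as.numeric(trimws(main[2]))
    if (is.na(rate) || rate < 0) stop("invalid rate in: ", r, call. = FALSE)
    sides <- strsplit(main[1], "->", fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("reaction must contain '->': ", r,
                                 call. = FALSE)
    lhs <- parse_side(sides[1]); rhs <- parse_side(sides[2])
    if (length(lhs) > 2) stop("reactant order must be <= 2: ", r,
                              call. = FALSE)
    list(lhs = lhs, rhs = rhs, rate = rate)
  })
  sp <- species %||% unique(unlist(lapply(parsed, function(p)
    c(p$lhs, p$rhs))))
  nr <- length(parsed)
  reactants <- products <- matrix(0L, length(sp), nr,
                                  dimnames = list(sp, NULL))
  for (k in seq_len(nr)) {
    for (s in parsed[[k]]$lhs) reactants[s, k] <- reactants[s, k] + 1L
    for (s in parsed[[k]]$rhs) products[s, k] <- products[s, k] + 1L
  }
  structure(list(species = sp, reactants = reactants, products = products,
                 rates = vapply(parsed, function(p) p$rate, numeric(1)),
                 labels = trimws(vapply(reactions, function(r)
                   strsplit(r, ",")[[1]][1], character(1)))),
            class = "reaction_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions\n",
              length(x$species), length(x$rates)))
  if (length(x$rates))
    cat(paste0("  ", x$labels, "  (rate ", x$rates, ")\n"), sep = "")
  invisible(x)
}

#' Mass-action propensities in one subvolume
#'
#' Unimolecular: \code{rate * n}; heterobimolecular:
#' \code{rate * nA * nB / h^2}; homobimolecular:
#' \code{rate * n * (n - 1) / (2 * h^2)}; zero order: \code{rate * h^2}.
#'
#' @param counts named numeric vector of per-species counts in the
#'   subvolume.
#' @param network a \code{\link{reaction_network}}.
#' @param spacing lattice spacing h (the subvolume measure is \code{h^2}).
#' @return numeric vector of per-reaction propensities.
#' @export
propensities <- function(counts, network, spacing) {
  vol <- spacing^2
  nr <- length(network$rates)
  out <- numeric(nr)
  for (k in seq_len(nr)) {
    r <- network$reactants[, k]
    order_k <- sum(r)
    if (order_k == 0) {
      out[k] <- network$rates[k] * vol
    } else if (order_k == 1) {
      s <- which(r == 1L)
      out[k] <- network$rates[k] * counts[[network$species[s]]]
    } else if (any(r == 2L)) {
      s <- which(r == 2L)
      n <- counts[[network$species[s]]]
      out[k] <- network$rates[k] * n * (n - 1) / (2 * vol)
    } else {
      ss <- which(r == 1L)
      out[k] <- network$rates[k] * counts[[network$species[ss[1]]]] *
        counts[[network$species[ss[2]]]] / vol
    }
  }
  out
}

#' Exact stochastic simulation of one subvolume
#'
#' Gillespie direct method: samples an exact path of the chemical master
#' equation for a single well-mixed subvolume over \code{[0, duration]}.
#'
#' @inheritParams propensities
#' @param duration time interval (>= 0).
#' @return updated named count vector.
#' @export
ssa_advance <- function(counts, network, duration, spacing) {
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  counts <- unlist(counts)[network$species]
  t_loc <- 0
  repeat {
    a <- propensities(as.list(counts), network, spacing)
    a0 <- sum(a)
    if (!is.finite(a0)) stop("propensity overflow in subvolume", call. = FALSE)
    if (a0 <= 0) break
    t_loc <- t_loc + stats::rexp(1, a0)
    if (t_loc > duration) break
    k <- sample.int(length(a), 1L, prob = a)
    counts <- counts - network$reactants[, k] + network$products[, k]
  }
  counts
}

#' Apply chemistry to every subvolume over one inter-event interval
#'
#' Runs \code{\link{ssa_advance}} independently in every subvolume with a
#' non-zero total propensity. Subvolume independence makes the cell ordering
#' irrelevant to the sampled distribution.
#'
#' @param state a \code{\link{lattice_state}}.
#' @param network a \code{\link{reaction_network}}.
#' @param interval time between consecutive diffusion events (>= 0).
#' @param domain a \code{\link{simulation_domain}}.
#' @return the updated \code{\link{lattice_state}}.
#' @export
react_between_events <- function(state, network, interval, domain) {
  if (interval == 0 || length(network$rates) == 0L) return(state)
  sp <- network$species
  missing_sp <- setdiff(sp, names(state$counts))
  if (length(missing_sp))
    stop("network references undefined species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  has_zero_order <- any(colSums(network$reactants) == 0)
  # cells worth visiting: any reactant present, or any zero-order source
  occupancy <- Reduce(`+`, lapply(sp, function(s) state$counts[[s]]))
  cells <- if (has_zero_order) seq_along(occupancy) else which(occupancy > 0)
  for (idx in cells) {
    cellcounts <- stats::setNames(
      vapply(sp, function(s) state$counts[[s]][idx], numeric(1)), sp)
    upd <- ssa_advance(as.list(cellcounts), network, interval, domain$spacing)
    for (s in sp) state$counts[[s]][idx] <- upd[[s]]
  }
  state
}
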