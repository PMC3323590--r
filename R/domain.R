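# Lattice geometry, coordinate conventions, boundary policies and state.
#
# The computational domain is a square of physical side length L divided into
# N x N subvolumes of spacing h = L/N. The cell-centered coordinate map is
# affine: the cell with (1-based R) index floor(N/2)+1 per axis sits at the
# configured origin, so with zero origin shift the origin lies at the center
# subvolume. An optional per-axis origin shift moves the whole coordinate
# system (used e.g. to make all coordinates strictly positive for processes
# with multiplicative noise). Axis 1 is x (matrix rows), axis 2 is y
# (matrix columns); file outputs use 0-based, row-major indices and state the
# convention in their headers.

#' Construct a simulation domain
#'
#' @param side_length physical width of the square domain (length units).
#' @param cells_per_dim number of subvolumes per dimension (integer >= 3).
#' @param boundary boundary policy: particles crossing the edge are removed
#'   (\code{"outflow"}), returned to their source cell (\code{"reflective"})
#'   or wrapped around (\code{"periodic"}).
#' @param origin_shift numeric length-2 per-axis offset added to all cell
#'   coordinates (length units).
#' @return an object of class \code{"simulation_domain"}.
#' @examples
#' dom <- simulation_domain(40, 64)
#' dom$spacing
#' @export
simulation_domain <- function(side_length, cells_per_dim,
                              boundary = c("outflow", "reflective", "periodic"),
                              origin_shift = c(0, 0)) {
  boundary <- match.arg(boundary)
  if (!is.numeric(side_length) || length(side_length) != 1L || side_length <= 0)
    stop("side_length must be a single positive number", call. = FALSE)
  cells_per_dim <- as.integer(cells_per_dim)
  if (is.na(cells_per_dim) || cells_per_dim < 3L)
    stop("cells_per_dim must be an integer >= 3", call. = FALSE)
  if (length(origin_shift) != 2L || any(!is.finite(origin_shift)))
    stop("origin_shift must be two finite numbers", call. = FALSE)
  structure(list(
    side_length = side_length,
    cells_per_dim = cells_per_dim,
    spacing = side_length / cells_per_dim,
    boundary = boundary,
    origin_shift = as.numeric(origin_shift)
  ), class = "simulation_domain")
}

#' @export
print.simulation_domain <- function(x, ...) {
  cat(sprintf(
    "<simulation_domain> %d x %d cells, side %g, spacing %g, %s boundaries\n",
    x$cells_per_dim, x$cells_per_dim, x$side_length, x$spacing, x$boundary))
  if (any(x$origin_shift != 0))
    cat(sprintf("  origin shift (%g, %g)\n",
                x$origin_shift[1], x$origin_shift[2]))
  invisible(x)
}

# center cell (1-based R index) per axis
center_index <- function(domain) floor(domain$cells_per_dim / 2) + 1L

#' Coordinates of all cell centers along one axis
#'
#' @param domain a \code{\link{simulation_domain}}.
#' @param axis 1 (x) or 2 (y).
#' @return numeric vector of length \code{cells_per_dim}.
#' @export
axis_coordinates <- function(domain, axis) {
  stopifnot(axis %in% c(1L, 2L))
  (seq_len(domain$cells_per_dim) - center_index(domain)) * domain$spacing +
    domain$origin_shift[axis]
}

#' Physical coordinates of cell centers
#'
#' Affine map from 1-based cell indices to physical positions; with zero
#' origin shift the center cell (index \code{floor(N/2)+1} per axis) maps to
#' the origin.
#'
#' @param index integer matrix or vector of cell indices; either a length-2
#'   vector \code{c(i, j)} or an n x 2 matrix of index pairs (1-based).
#' @param domain a \code{\link{simulation_domain}}.
#' @return numeric n x 2 matrix of positions.
#' @export
cell_center_coordinates <- function(index, domain) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 2)
  if (any(idx < 1L) || any(idx > domain$cells_per_dim))
    stop("cell index out of range", call. = FALSE)
  c0 <- center_index(domain)
  cbind(
    (idx[, 1] - c0) * domain$spacing + domain$origin_shift[1],
    (idx[, 2] - c0) * domain$spacing + domain$origin_shift[2]
  )
}

#' Nearest cell index for physical positions
#'
#' Inverse of \code{\link{cell_center_coordinates}}; positions are assigned
#' to the cell with the nearest center.
#'
#' @param position numeric n x 2 matrix (or length-2 vector) of positions.
#' @param domain a \code{\link{simulation_domain}}.
#' @return integer n x 2 matrix of 1-based indices.
#' @export
nearest_cell_index <- function(position, domain) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  c0 <- center_index(domain)
  idx <- cbind(
    as.integer(round((pos[, 1] - domain$origin_shift[1]) / domain$spacing)) + c0,
    as.integer(round((pos[, 2] - domain$origin_shift[2]) / domain$spacing)) + c0
  )
  if (any(idx < 1L) || any(idx > domain$cells_per_dim))
    stop("position outside the domain", call. = FALSE)
  idx
}

#' Construct a lattice state
#'
#' A lattice state holds one non-negative integer count matrix per species
#' plus the global clock time.
#'
#' @param counts a named list of integer matrices (one per species), or a
#'   single matrix for a single species named \code{"A"}.
#' @param time global clock time (>= 0).
#' @return an object of class \code{"lattice_state"}.
#' @export
lattice_state <- function(counts, time = 0) {
  if (is.matrix(counts)) counts <- list(A = counts)
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("species matrices must be named", call. = FALSE)
  for (s in names(counts)) {
    m <- counts[[s]]
    if (!is.matrix(m) || any(m < 0) || any(m != round(m)))
      stop("counts must be matrices of non-negative integers", call. = FALSE)
    storage.mode(counts[[s]]) <- "double"  # counts can exceed integer range sums
  }
  structure(list(counts = counts, time = time), class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  tot <- vapply(x$counts, sum, numeric(1))
  cat(sprintf("<lattice_state> t = %g; %s\n", x$time,
              paste(sprintf("%s: %g particles", names(tot), tot),
                    collapse = ", ")))
  invisible(x)
}

#' Total particle count per species
#'
#' @param state a \code{\link{lattice_state}}.
#' @return named numeric vector of totals.
#' @export
total_counts <- function(state) {
  vapply(state$counts, sum, numeric(1))
}

#' Place an initial condition on the lattice
#'
#' Supported placements: a point source (all particles in the cell containing
#' the given center), a uniform disc (particles distributed as evenly as
#' possible over all cells whose centers fall inside the disc, remainder
#' assigned in lexicographic index order), and a uniform field over the whole
#' lattice. The total placed count always equals \code{count} exactly.
#'
#' @param domain a \code{\link{simulation_domain}}.
#' @param type one of \code{"point"}, \code{"disc"}, \code{"uniform"}.
#' @param count total number of particles to place.
#' @param center physical coordinates of the source (point and disc).
#' @param radius disc radius (length units); a radius smaller than half a
#'   cell degenerates to a point source.
#' @param species species name for the placed particles.
#' @return a \code{\link{lattice_state}} at time 0.
#' @export
place_initial_condition <- function(domain,
                                    type = c("point", "disc", "uniform"),
                                    count, center = c(0, 0), radius = 0,
                                    species = "A") {
  type <- match.arg(type)
  n <- domain$cells_per_dim
  m <- matrix(0, n, n)
  count <- round(count)
  if (count < 0) stop("count must be non-negative", call. = FALSE)
  if (type == "point" || (type == "disc" && radius <= 0)) {
    idx <- nearest_cell_index(center, domain)
    m[idx[1, 1], idx[1, 2]] <- count
  } else if (type == "disc") {
    xs <- axis_coordinates(domain, 1)
    ys <- axis_coordinates(domain, 2)
    inside <- outer(xs, ys, function(x, y)
      (x - center[1])^2 + (y - center[2])^2 <= radius^2)
    k <- sum(inside)
    if (k == 0) {
      idx <- nearest_cell_index(center, domain)
      m[idx[1, 1], idx[1, 2]] <- count
    } else {
      base <- count %/% k
      rem <- count %% k
      # lexicographic (row-major in 0-based x-fastest order): order by
      # column-major linear index of the transposed test -> iterate x first
      cells <- which(inside, arr.ind = TRUE)
      ord <- order(cells[, 1], cells[, 2])
      cells <- cells[ord, , drop = FALSE]
      m[cells] <- base
      if (rem > 0) m[cells[seq_len(rem), , drop = FALSE]] <-
          m[cells[seq_len(rem), , drop = FALSE]] + 1
    }
  } else {
    k <- n * n
    base <- count %/% k
    rem <- count %% k
    m[] <- base
    if (rem > 0) m[seq_len(rem)] <- m[seq_len(rem)] + 1
  }
  stats::setNames(list(m), species) |> lattice_state(time = 0)
}

#' Resolve a lattice jump under a boundary policy
#'
#' Interior jumps go to the nearest neighbor along the axis; jumps across
#' the domain edge follow the policy: removed under outflow, returned to the
#' source cell under reflective, wrapped under periodic.
#'
#' @param index length-2 integer cell index (1-based).
#' @param axis 1 (x) or 2 (y).
#' @param direction +1 or -1.
#' @param domain a \code{\link{simulation_domain}}.
#' @return the target index (length-2 integer vector), or \code{NULL} if the
#'   particle is removed (outflow).
#' @export
resolve_jump <- function(index, axis, direction, domain) {
  n <- domain$cells_per_dim
  target <- index
  target[axis] <- index[axis] + direction
  if (target[axis] >= 1L && target[axis] <= n) return(target)
  switch(domain$boundary,
    outflow = NULL,
    reflective = index,
    periodic = { target[axis] <- ((target[axis] - 1L) %% n) + 1L; target }
  )
}

#' Per-cell concentrations
#'
#' Particle counts divided by the subvolume measure \code{spacing^2}.
#'
#' @param state a \code{\link{lattice_state}}.
#' @param domain a \code{\link{simulation_domain}}.
#' @return named list of density matrices, one per species.
#' @export
densities <- function(state, domain) {
  lapply(state$counts, function(m) m / domain$spacing^2)
}
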