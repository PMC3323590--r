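# Configuration parsing, validation and deterministic output writing.
#
# Configurations are plain lists (YAML on disk). All randomness flows from
# the single base seed in the configuration; a missing seed is a validation
# error. Output files never contain timestamps, so identical configurations
# and seeds yield byte-identical files.

.config_keys <- c("problem", "cells_per_dim", "side_length", "kernel",
                  "boundary", "t_end", "snapshot_times", "runs", "seed",
                  "count", "origin", "origin_shift", "params", "reactions")

#' Validate a run configuration
#'
#' @param cfg a configuration list.
#' @return the validated configuration (class \code{"run_config"}),
#'   invisibly usable in pipelines.
#' @export
validate_config <- function(cfg) {
  cfg <- unclass(cfg)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  need <- c("problem", "seed", "cells_per_dim", "kernel", "runs",
            "side_length", "t_end", "boundary")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("missing required configuration keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!cfg$problem %in% c("homogeneous", "gbm", "ou", "nonlinear",
                          "migration"))
    stop("invalid value for field 'problem': ", cfg$problem, call. = FALSE)
  if (!cfg$kernel %in% c("fpt", "fpe"))
    stop("invalid value for field 'kernel': ", cfg$kernel, call. = FALSE)
  if (!cfg$boundary %in% c("outflow", "reflective", "periodic"))
    stop("invalid value for field 'boundary': ", cfg$boundary, call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed))
    stop("seed must be an integer (all randomness derives from it)",
         call. = FALSE)
  if (cfg$runs < 1) stop("runs must be >= 1", call. = FALSE)
  if (cfg$t_end < 0) stop("t_end must be >= 0", call. = FALSE)
  if (is.null(cfg$snapshot_times)) cfg$snapshot_times <- cfg$t_end
  if (any(cfg$snapshot_times > cfg$t_end))
    stop("snapshot times must not exceed t_end", call. = FALSE)
  if (is.null(cfg$origin_shift)) cfg$origin_shift <- c(0, 0)
  if (is.null(cfg$origin)) cfg$origin <- c(0, 0)
  structure(cfg, class = "run_config")
}

#' Parse a configuration from YAML
#'
#' Reads a YAML document (file path or literal text), merges it onto the
#' named problem's defaults and validates the result. Unknown keys are
#' rejected.
#'
#' @param text YAML text, or a path to a YAML file.
#' @return a validated configuration list.
#' @export
parse_config <- function(text) {
  raw <- if (length(text) == 1L && file.exists(text))
    yaml::read_yaml(text) else yaml::yaml.load(paste(text, collapse = "\n"))
  if (is.null(raw$problem)) stop("configuration must name a problem",
                                 call. = FALSE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$seed))
    stop("missing required configuration keys: seed", call. = FALSE)
  args <- raw[setdiff(names(raw), c("problem", "params"))]
  base <- do.call(benchmark_config, c(
    list(problem = raw$problem,
         cells_per_dim = raw$cells_per_dim %||% 64,
         kernel = raw$kernel %||% "fpt",
         runs = raw$runs %||% 100,
         seed = raw$seed),
    args[setdiff(names(args), c("cells_per_dim", "kernel", "runs", "seed"))]))
  for (nm in names(raw$params)) base$params[[nm]] <- raw$params[[nm]]
  validate_config(base)
}

#' Serialize a configuration to YAML
#'
#' Round-trips through \code{\link{parse_config}} to an equivalent
#' configuration.
#'
#' @param cfg a validated configuration.
#' @return a YAML string.
#' @export
serialize_config <- function(cfg) {
  cfg <- unclass(validate_config(cfg))
  cfg$params <- lapply(cfg$params, function(v)
    if (inherits(v, "migration_parameters")) unclass(v) else v)
  if (inherits(cfg$params, "migration_parameters"))
    cfg$params <- unclass(cfg$params)
  yaml::as.yaml(cfg)
}

#' Write a lattice snapshot as a plain-text matrix
#'
#' The header (lines prefixed \code{#}) records time, spacing, boundary,
#' seed, species and the index convention; the body is the count matrix,
#' written as integers when all entries are whole and at full double
#' precision otherwise.
#'
#' @param counts N x N matrix.
#' @param path output file.
#' @param meta named list with at least \code{time}, \code{spacing},
#'   \code{boundary}, \code{seed}, \code{species}.
#' @export
write_snapshot <- function(counts, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# time: %.17g", meta$time),
    sprintf("# spacing: %.17g", meta$spacing),
    sprintf("# boundary: %s", meta$boundary),
    sprintf("# seed: %d", meta$seed),
    sprintf("# species: %s", meta$species),
    "# layout: rows are x (axis 1), columns are y (axis 2); 0-based indices, row-major"
  ), con)
  whole <- all(counts == round(counts))
  fmt <- if (whole) "%d" else "%.17g"
  apply(counts, 1, function(row) {
    if (whole) paste(sprintf(fmt, as.integer(round(row))), collapse = " ")
    else paste(sprintf(fmt, row), collapse = " ")
  }) |> writeLines(con)
}

#' Read a snapshot written by \code{\link{write_snapshot}}
#'
#' @param path snapshot file.
#' @return matrix with attribute \code{meta} (named list of header fields).
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^# ([a-z]+): (.*)$", l))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  attr(mat, "meta") <- meta
  mat
}

# write snapshots, report and manifest for a finished benchmark
write_benchmark_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  files <- character(0)
  cfg_path <- file.path(out_dir, "config.yaml")
  writeLines(serialize_config(cfg), cfg_path)
  files <- c(files, "config.yaml")
  sp_names <- names(result$mean[[1]])
  for (k in seq_along(result$mean)) {
    tt <- as.numeric(names(result$mean)[k])
    for (s in sp_names) {
      fn <- sprintf("mean_%s_snapshot%02d.txt", s, k)
      write_snapshot(result$mean[[k]][[s]], file.path(out_dir, fn),
                     list(time = tt, spacing = result$domain$spacing,
                          boundary = cfg$boundary, seed = cfg$seed,
                          species = s))
      files <- c(files, fn)
    }
  }
  rp <- file.path(out_dir, "report.tsv")
  utils::write.table(format(result$report, digits = 17),
                     rp, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "report.tsv")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "mesodrift",
    version = as.character(utils::packageVersion("mesodrift")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = stats::setNames(as.list(unname(sums)), files))
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Quick look at a lattice state
#'
#' Base-graphics image of one species' counts with physical axes.
#'
#' @param state a \code{\link{lattice_state}}.
#' @param domain a \code{\link{simulation_domain}}.
#' @param species species to plot.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot_lattice_state <- function(state, domain, species = names(state$counts)[1],
                               ...) {
  graphics::image(axis_coordinates(domain, 1), axis_coordinates(domain, 2),
                  state$counts[[species]], xlab = "x", ylab = "y",
                  main = sprintf("%s at t = %g", species, state$time), ...)
}
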