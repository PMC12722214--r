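#' Define a simulation parameter grid
#'
#' A named collection of parameter value lists whose Cartesian product
#' defines the rows of a simulated dictionary. Recognized names are
#' `water_t1`, `water_t2` (s), `f_ss`, `k_ssw`, `f_rnoe`, `k_rnoe`,
#' `f_amide`, `k_amide` (fractions / 1 s), `glu_mM` (glutamate concentration
#' in mM, converted to an amine proton volume fraction for simulation via
#' [glu_conc_to_fraction()]) and `k_glu` (1/s).
#'
#' @param ... Named numeric vectors of grid values.
#' @param duplicates `"dedup"` silently drops duplicated values within a
#'   list (reporting the count); `"error"` rejects them.
#' @return An object of class `cest_grid`.
#' @examples
#' parameter_grid(water_t1 = c(1.4, 2), f_ss = c(0.05, 0.1, 0.2),
#'                k_ssw = c(20, 50))
#' @export
parameter_grid <- function(..., duplicates = c("dedup", "error")) {
  duplicates <- match.arg(duplicates)
  values <- list(...)
  if (length(values) == 1L && is.list(values[[1]]) &&
      is.null(names(values))) values <- values[[1]]
  known <- c("water_t1", "water_t2", "f_ss", "k_ssw", "f_rnoe", "k_rnoe",
             "f_amide", "k_amide", "glu_mM", "k_glu")
  if (is.null(names(values)) || any(names(values) == ""))
    stop("all grid components must be named")
  bad <- setdiff(names(values), known)
  if (length(bad))
    stop("unknown grid parameter(s): ", paste(bad, collapse = ", "))
  ndup <- 0L
  for (nm in names(values)) {
    v <- as.numeric(values[[nm]])
    if (!length(v) || any(!is.finite(v)))
      stop("grid values for '", nm, "' must be non-empty and finite")
    if (anyDuplicated(v)) {
      if (duplicates == "error")
        stop("duplicated values in grid parameter '", nm, "'")
      ndup <- ndup + sum(duplicated(v))
      v <- unique(v)
    }
    if (startsWith(nm, "f_") && any(v < 0 | v >= 1))
      stop("'", nm, "' values must be in [0, 1)")
    if (startsWith(nm, "k_") && any(v < 0))
      stop("'", nm, "' values must be >= 0")
    if (nm %in% c("water_t1", "water_t2") && any(v <= 0))
      stop("'", nm, "' values must be positive")
    if (nm == "glu_mM" && any(v < 0))
      stop("'glu_mM' values must be >= 0")
    values[[nm]] <- v
  }
  if (ndup > 0) message(ndup, " duplicated grid value(s) removed")
  structure(list(values = values), class = "cest_grid")
}

#' @export
print.cest_grid <- function(x, ...) {
  cat(sprintf("<cest_grid> %d parameters, %d combinations\n",
              length(x$values), grid_size(x)))
  for (nm in names(x$values)) {
    v <- x$values[[nm]]
    cat(sprintf("  %-9s %3d values in [%g, %g]\n", nm, length(v), min(v),
                max(v)))
  }
  invisible(x)
}

#' Number of Cartesian-product combinations in a grid
#' @param grid A [parameter_grid()].
#' @export
grid_size <- function(grid) {
  prod(vapply(grid$values, length, integer(1)))
}

#' Shipped default parameter grids
#'
#' Reads the per-network default grid shipped with the package
#' (`inst/extdata/grids/`). Ranges bracket values reported for brain tissue
#' and in vitro glutamate at 7 T; the default water T2 range deliberately
#' excludes CSF-like values (a wide-T2 variant of the semisolid MT grid,
#' `"mt_wide_t2"`, is provided separately).
#'
#' @param network `"mt"`, `"rnoe"`, `"amideglu"`, or `"mt_wide_t2"`.
#' @return A [parameter_grid()].
#' @export
default_grid <- function(network = c("mt", "rnoe", "amideglu",
                                     "mt_wide_t2")) {
  network <- match.arg(network)
  read_grid(system.file("extdata", "grids",
                        paste0(network, "_grid.yaml"),
                        package = "cestmrf", mustWork = TRUE))
}

#' Read or write a parameter grid as YAML
#' @param grid A [parameter_grid()].
#' @param path File path.
#' @export
write_grid <- function(grid, path) {
  yaml::write_yaml(grid$values, path, precision = 15)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  parameter_grid(lapply(yaml::read_yaml(path), as.numeric))
}

#' Thin a grid for reduced-scale runs
#'
#' Keeps every `by`-th value (always retaining the endpoints) of the listed
#' parameters, reducing dictionary size while preserving coverage.
#'
#' @param grid A [parameter_grid()].
#' @param by Integer thinning factor.
#' @param only Optional character vector restricting which parameters are
#'   thinned.
#' @export
thin_grid <- function(grid, by = 2, only = NULL) {
  vals <- grid$values
  for (nm in names(vals)) {
    if (!is.null(only) && !(nm %in% only)) next
    v <- vals[[nm]]
    if (length(v) <= 2) next
    keep <- unique(c(seq(1, length(v), by = by), length(v)))
    vals[[nm]] <- v[keep]
  }
  parameter_grid(vals)
}

# Base tissue for a dictionary: keep the water and semisolid pools plus
# only the mobile pools the grid references. Protocol-irrelevant mobile
# pools sit many linewidths off resonance and contribute negligibly, so
# dropping them keeps the per-stage Bloch-McConnell system small.
.grid_base_tissue <- function(grid, full_tissue = phantom_base_tissue()) {
  nms <- names(grid$values)
  keep <- character(0)
  if (any(nms %in% c("f_amide", "k_amide"))) keep <- c(keep, "amide")
  # the glutamate protocol samples mirrored negative offsets, where the
  # aliphatic rNOE tail contributes; keep that pool (fixed) in the model
  if (any(nms %in% c("glu_mM", "k_glu"))) keep <- c(keep, "glu", "rnoe")
  if (any(nms %in% c("f_rnoe", "k_rnoe"))) keep <- c(keep, "rnoe")
  tissue_model(full_tissue$water_t1, full_tissue$water_t2,
               full_tissue$solute_pools[intersect(names(full_tissue$solute_pools), keep)],
               full_tissue$semisolid, full_tissue$b0_shift)
}

# Map grid parameter names to (target, field) roles for the C++ core.
# target: 0 water, -1 semisolid, >= 1 index of the named solute pool.
.grid_roles <- function(grid, tissue) {
  nms <- names(grid$values)
  pool_idx <- function(p) {
    i <- match(p, names(tissue$solute_pools))
    if (is.na(i))
      stop("grid references pool '", p, "' absent from the base tissue")
    i
  }
  tgt <- integer(length(nms)); fld <- integer(length(nms))
  for (j in seq_along(nms)) {
    nm <- nms[j]
    if (nm == "water_t1") { tgt[j] <- 0L; fld[j] <- 1L }
    else if (nm == "water_t2") { tgt[j] <- 0L; fld[j] <- 2L }
    else if (nm == "f_ss") { tgt[j] <- -1L; fld[j] <- 4L }
    else if (nm == "k_ssw") { tgt[j] <- -1L; fld[j] <- 3L }
    else if (nm == "f_rnoe") { tgt[j] <- pool_idx("rnoe"); fld[j] <- 4L }
    else if (nm == "k_rnoe") { tgt[j] <- pool_idx("rnoe"); fld[j] <- 3L }
    else if (nm == "f_amide") { tgt[j] <- pool_idx("amide"); fld[j] <- 4L }
    else if (nm == "k_amide") { tgt[j] <- pool_idx("amide"); fld[j] <- 3L }
    else if (nm == "glu_mM") { tgt[j] <- pool_idx("glu"); fld[j] <- 4L }
    else if (nm == "k_glu") { tgt[j] <- pool_idx("glu"); fld[j] <- 3L }
  }
  if (any(tgt == -1L) && is.null(tissue$semisolid))
    stop("grid varies semisolid parameters but the base tissue has none")
  list(target = tgt, field = fld)
}

#' Generate a simulated MRF dictionary
#'
#' Simulates one signal trajectory per Cartesian-product combination of the
#' grid, in deterministic row order (the first declared parameter varies
#' fastest), starting from `base_tissue` with the grid-varied parameters
#' overridden row by row. Results are identical for any worker count.
#'
#' @param grid A [parameter_grid()].
#' @param schedule A [acquisition_schedule()] (or, for the combined
#'   amide/glutamate network, a named list of two schedules whose
#'   trajectories are concatenated per row).
#' @param base_tissue Tissue model providing all non-varied parameters;
#'   by default it is derived from [phantom_base_tissue()], keeping water,
#'   the semisolid pool, and the mobile pools the grid references (other
#'   mobile pools sit far off resonance for the stage's protocol and are
#'   omitted from the simulation).
#' @param workers Number of parallel workers (forked; results are
#'   reassembled in order and do not depend on `workers`).
#' @param max_rows Guard against accidental memory blow-up: grids larger
#'   than this are rejected with an explicit size error.
#' @return An object of class `cest_dictionary` with elements `grid`,
#'   `params` (rows of parameter combinations), `traj` (rows of simulated
#'   trajectories), `normalized` (unit-norm encoding vectors, see
#'   [l2_normalize()]), `schedule_hash`, and `schedule_id`.
#' @examples
#' g <- parameter_grid(f_ss = c(0.05, 0.15), k_ssw = c(20, 60))
#' d <- generate_dictionary(g, default_schedule("mt"))
#' nrow(d$params)
#' @export
generate_dictionary <- function(grid, schedule, base_tissue = NULL,
                                workers = 1, max_rows = 2e6) {
  stopifnot(inherits(grid, "cest_grid"))
  if (is.null(base_tissue)) base_tissue <- .grid_base_tissue(grid)
  n <- grid_size(grid)
  if (n > max_rows)
    stop(sprintf("grid has %d rows, exceeding the %d-row budget", n,
                 max_rows))
  schedules <- if (inherits(schedule, "cest_schedule")) list(schedule)
               else schedule
  stopifnot(all(vapply(schedules, inherits, logical(1), "cest_schedule")))
  params <- as.matrix(expand.grid(grid$values, KEEP.OUT.ATTRS = FALSE))
  sim_params <- params
  if ("glu_mM" %in% colnames(params))
    sim_params[, "glu_mM"] <- glu_conc_to_fraction(params[, "glu_mM"])
  roles <- .grid_roles(grid, base_tissue)
  tc <- .tissue_cpp(base_tissue)
  sim_one <- function(rows, sched) {
    .bm_dictionary(tc, sim_params[rows, , drop = FALSE], roles$target,
                   roles$field, .schedule_matrix(sched), sched$b0_field)
  }
  traj <- lapply(schedules, function(sched) {
    if (workers > 1) {
      chunks <- split(seq_len(n), cut(seq_len(n), workers, labels = FALSE))
      do.call(rbind, parallel::mclapply(chunks, sim_one, sched = sched,
                                        mc.cores = workers))
    } else sim_one(seq_len(n), sched)
  })
  names(traj) <- vapply(schedules, `[[`, character(1), "id")
  normalized <- lapply(traj, l2_normalize)
  if (length(traj) == 1L) { traj <- traj[[1]]; normalized <- normalized[[1]] }
  structure(list(grid = grid, params = params, traj = traj,
                 normalized = normalized,
                 schedule_hash = vapply(schedules, schedule_hash,
                                        character(1)),
                 schedule_id = vapply(schedules, `[[`, character(1), "id"),
                 b0_field = schedules[[1]]$b0_field),
            class = "cest_dictionary")
}

#' @export
print.cest_dictionary <- function(x, ...) {
  cat(sprintf("<cest_dictionary> %d rows x %d parameters (%s), schedule(s): %s\n",
              nrow(x$params), ncol(x$params),
              paste(colnames(x$params), collapse = ", "),
              paste(x$schedule_id, collapse = " + ")))
  invisible(x)
}

#' L2-normalize MRF trajectories into encoding vectors
#'
#' The saturated entries are divided by the M0 (first) entry and the result
#' is scaled to unit Euclidean norm. With `use_m0 = FALSE` the whole vector
#' is normalized without M0 referencing.
#'
#' @param x A numeric trajectory (M0 first), a matrix with one trajectory
#'   per row, or a `cest_trajectory`.
#' @param use_m0 Divide by the M0 entry and drop it (default `TRUE`).
#' @return A unit-norm vector (or matrix of unit-norm rows).
#' @examples
#' l2_normalize(c(1, 3, 4))   # -> 0.6 0.8
#' @export
l2_normalize <- function(x, use_m0 = TRUE) {
  if (inherits(x, "cest_trajectory")) x <- x$values
  if (is.matrix(x)) {
    sat <- if (use_m0) x[, -1, drop = FALSE] / x[, 1] else x
    nrm <- sqrt(rowSums(sat^2))
    if (any(nrm == 0)) stop("zero-norm trajectory cannot be normalized")
    return(sat / nrm)
  }
  sat <- if (use_m0) x[-1] / x[1] else x
  nrm <- sqrt(sum(sat^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("zero-norm trajectory cannot be normalized")
  sat / nrm
}

#' Save or load a dictionary container
#'
#' Dictionaries are stored as a single self-describing binary container
#' (serialized R object) holding the parameter matrix, trajectory matrix,
#' normalized encoding matrix, grid definition and schedule hash; the
#' round-trip is bit-exact.
#'
#' @param dictionary A `cest_dictionary`.
#' @param path File path (conventionally `.rds`).
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "cest_dictionary"))
  saveRDS(dictionary, path, version = 3)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "cest_dictionary"))
  x
}
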