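#' Define a mobile solute proton pool
#'
#' A mobile (free) solute pool exchanging with water, described by its
#' chemical shift, relaxation times, solute-to-water exchange rate
#' \eqn{k_{sw}} and proton volume fraction \eqn{f_s} (relative to a water
#' fraction of 1). The reverse (water-to-solute) rate follows from mass
#' balance, \eqn{k_{ws} = f_s k_{sw}}.
#'
#' @param name Pool label, e.g. `"amide"`.
#' @param chemical_shift Chemical shift in ppm relative to water (positive =
#'   downfield; amide +3.5, glutamate amine +3, aliphatic rNOE -3.5).
#' @param t1,t2 Longitudinal and transverse relaxation times in seconds.
#' @param exchange_rate Solute-to-water exchange rate \eqn{k_{sw}} in 1/s.
#' @param volume_fraction Proton volume fraction \eqn{f_s}, dimensionless,
#'   in `[0, 1)`.
#' @return An object of class `cest_pool`.
#' @examples
#' pool("amide", 3.5, t1 = 1, t2 = 0.01, exchange_rate = 200,
#'      volume_fraction = 0.005)
#' @export
pool <- function(name, chemical_shift, t1, t2, exchange_rate,
                 volume_fraction) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(chemical_shift, t1, t2, exchange_rate, volume_fraction)
  if (any(!is.finite(vals))) stop("pool parameters must be finite")
  if (t1 <= 0 || t2 <= 0) stop("'t1' and 't2' must be positive")
  if (exchange_rate < 0) stop("'exchange_rate' must be non-negative")
  if (volume_fraction < 0 || volume_fraction >= 1)
    stop("'volume_fraction' must be in [0, 1)")
  structure(list(name = name, chemical_shift = chemical_shift, t1 = t1,
                 t2 = t2, exchange_rate = exchange_rate,
                 volume_fraction = volume_fraction),
            class = "cest_pool")
}

#' Define the semisolid magnetization-transfer pool
#'
#' The motion-restricted macromolecular pool is modeled as
#' longitudinal-only; its saturation by RF is governed by an absorption
#' lineshape \eqn{g(\Delta\omega)} (Lorentzian or super-Lorentzian) through
#' the rate \eqn{\pi \omega_1^2 g(\Delta\omega)}. Parameters are the
#' volume fraction \eqn{f_{ss}} and exchange rate \eqn{k_{ssw}}.
#'
#' @inheritParams pool
#' @param t2 Transverse relaxation time in seconds, on the microsecond scale
#'   (must be `<= 1e-3`).
#' @param lineshape `"super_lorentzian"` (default) or `"lorentzian"`. The
#'   super-Lorentzian on-resonance singularity is bridged by interpolation
#'   over +/- 1 ppm around the pool center.
#' @return An object of class `cest_semisolid`.
#' @examples
#' semisolid_pool(volume_fraction = 0.1, exchange_rate = 40)
#' @export
semisolid_pool <- function(volume_fraction, exchange_rate,
                           chemical_shift = 0, t1 = 1, t2 = 10e-6,
                           lineshape = c("super_lorentzian", "lorentzian")) {
  lineshape <- match.arg(lineshape)
  vals <- c(chemical_shift, t1, t2, exchange_rate, volume_fraction)
  if (any(!is.finite(vals))) stop("semisolid parameters must be finite")
  if (t1 <= 0 || t2 <= 0) stop("'t1' and 't2' must be positive")
  if (t2 > 1e-3)
    stop("semisolid 't2' must be <= 1e-3 s (microsecond scale)")
  if (exchange_rate < 0) stop("'exchange_rate' must be non-negative")
  if (volume_fraction < 0 || volume_fraction >= 1)
    stop("'volume_fraction' must be in [0, 1)")
  structure(list(name = "semisolid", chemical_shift = chemical_shift,
                 t1 = t1, t2 = t2, exchange_rate = exchange_rate,
                 volume_fraction = volume_fraction, lineshape = lineshape),
            class = "cest_semisolid")
}

#' Assemble a multi-pool tissue model
#'
#' Combines the water pool, mobile solute pools, and an optional semisolid
#' pool into the parameter vector the quantification pipeline estimates.
#' Exchange topology is star-shaped: every solute exchanges with water only.
#'
#' @param water_t1,water_t2 Water relaxation times in seconds
#'   (`water_t1 >= water_t2`).
#' @param solute_pools List of [pool()] objects (may be empty).
#' @param semisolid Optional [semisolid_pool()].
#' @param b0_shift Local static-field offset in ppm; it is added to every
#'   pool's chemical shift, so a spectrum minimum appears at `+b0_shift`.
#' @return An object of class `cest_tissue`.
#' @examples
#' tissue_model(1.8, 0.055,
#'              solute_pools = list(pool("amide", 3.5, 1, 0.01, 200, 0.003)),
#'              semisolid = semisolid_pool(0.1, 40))
#' @export
tissue_model <- function(water_t1, water_t2, solute_pools = list(),
                         semisolid = NULL, b0_shift = 0) {
  if (!is.finite(water_t1) || !is.finite(water_t2) || water_t1 <= 0 ||
      water_t2 <= 0)
    stop("water relaxation times must be positive and finite")
  if (water_t1 < water_t2) stop("'water_t1' must be >= 'water_t2'")
  if (!is.list(solute_pools) ||
      !all(vapply(solute_pools, inherits, logical(1), "cest_pool")))
    stop("'solute_pools' must be a list of cest_pool objects")
  if (!is.null(semisolid) && !inherits(semisolid, "cest_semisolid"))
    stop("'semisolid' must be a cest_semisolid object or NULL")
  if (!is.finite(b0_shift)) stop("'b0_shift' must be finite")
  fsum <- sum(vapply(solute_pools, `[[`, numeric(1), "volume_fraction")) +
    if (is.null(semisolid)) 0 else semisolid$volume_fraction
  if (fsum >= 1)
    stop("sum of solute and semisolid volume fractions must be < 1")
  nm <- vapply(solute_pools, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("solute pool names must be unique")
  structure(list(water_t1 = water_t1, water_t2 = water_t2,
                 solute_pools = stats::setNames(solute_pools, nm),
                 semisolid = semisolid, b0_shift = b0_shift),
            class = "cest_tissue")
}

#' @export
print.cest_tissue <- function(x, ...) {
  cat(sprintf("<cest_tissue> water T1/T2 = %.3g/%.3g s, b0 shift = %+.3g ppm\n",
              x$water_t1, x$water_t2, x$b0_shift))
  for (p in x$solute_pools)
    cat(sprintf("  %-10s %+0.2f ppm  k_sw = %g 1/s  f_s = %g\n",
                p$name, p$chemical_shift, p$exchange_rate, p$volume_fraction))
  if (!is.null(x$semisolid))
    cat(sprintf("  semisolid  %+0.2f ppm  k_ssw = %g 1/s  f_ss = %g  (%s)\n",
                x$semisolid$chemical_shift, x$semisolid$exchange_rate,
                x$semisolid$volume_fraction, x$semisolid$lineshape))
  invisible(x)
}

# Flatten a tissue model into the list the C++ core consumes.
.tissue_cpp <- function(tissue) {
  stopifnot(inherits(tissue, "cest_tissue"))
  np <- length(tissue$solute_pools)
  pools <- matrix(0, nrow = 5, ncol = np)
  for (j in seq_len(np)) {
    p <- tissue$solute_pools[[j]]
    pools[, j] <- c(p$chemical_shift, p$t1, p$t2, p$exchange_rate,
                    p$volume_fraction)
  }
  ss <- NULL
  if (!is.null(tissue$semisolid)) {
    s <- tissue$semisolid
    ss <- c(s$chemical_shift, s$t1, s$t2, s$exchange_rate,
            s$volume_fraction,
            if (s$lineshape == "lorentzian") 0 else 1)
  }
  list(water = c(tissue$water_t1, tissue$water_t2), pools = pools,
       semisolid = ss, b0_shift = tissue$b0_shift)
}

#' Serialize a tissue model to or from YAML
#'
#' @param tissue A [tissue_model()].
#' @param path File path.
#' @return `read_tissue` returns a `cest_tissue`; `write_tissue` returns
#'   `path` invisibly.
#' @export
write_tissue <- function(tissue, path) {
  stopifnot(inherits(tissue, "cest_tissue"))
  x <- list(water_t1 = tissue$water_t1, water_t2 = tissue$water_t2,
            b0_shift = tissue$b0_shift,
            solute_pools = lapply(unname(tissue$solute_pools), unclass))
  if (!is.null(tissue$semisolid)) x$semisolid <- unclass(tissue$semisolid)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_tissue
#' @export
read_tissue <- function(path) {
  x <- yaml::read_yaml(path)
  pools <- lapply(x$solute_pools, function(p)
    pool(p$name, p$chemical_shift, p$t1, p$t2, p$exchange_rate,
         p$volume_fraction))
  ss <- NULL
  if (!is.null(x$semisolid))
    ss <- semisolid_pool(x$semisolid$volume_fraction,
                         x$semisolid$exchange_rate,
                         x$semisolid$chemical_shift, x$semisolid$t1,
                         x$semisolid$t2, x$semisolid$lineshape)
  tissue_model(x$water_t1, x$water_t2, pools, ss, x$b0_shift %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
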