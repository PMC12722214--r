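#' Convert glutamate concentration to an amine proton volume fraction
#'
#' Glutamate contributes `protons_per_molecule` exchangeable amine protons
#' (chemical shift +3 ppm) per molecule; relative to the water proton
#' concentration of 2 x 55.5 M = 111,000 mM, a concentration `c` mM maps to
#' a volume fraction `f = protons_per_molecule * c / 111000`.
#'
#' @param concentration Concentration in mM (>= 0; vectorized).
#' @param protons_per_molecule Exchangeable protons per molecule (default 3).
#' @return Dimensionless proton volume fraction.
#' @examples
#' glu_conc_to_fraction(20)       # 5.405e-4
#' fraction_to_glu_conc(glu_conc_to_fraction(12.5))
#' @export
glu_conc_to_fraction <- function(concentration, protons_per_molecule = 3) {
  if (any(concentration < 0)) stop("'concentration' must be >= 0")
  protons_per_molecule * concentration / 111000
}

#' @rdname glu_conc_to_fraction
#' @param fraction Proton volume fraction (>= 0).
#' @export
fraction_to_glu_conc <- function(fraction, protons_per_molecule = 3) {
  if (any(fraction < 0)) stop("'fraction' must be >= 0")
  fraction * 111000 / protons_per_molecule
}

#' Base tissue model for phantoms and dictionaries
#'
#' Brain-like 7 T defaults for all parameters that the phantom and the
#' dictionary grids do not vary: water T1/T2 1.8 s / 55 ms; amide pool at
#' +3.5 ppm (k 200 1/s, f 0.3%); glutamate amine pool at +3 ppm (k 7000
#' 1/s, 10 mM); aliphatic rNOE pool at -3.5 ppm (k 20 1/s, f 1%); and a
#' super-Lorentzian semisolid pool (T2 10 us, k_ssw 40 1/s, f_ss 10%).
#'
#' @return A [tissue_model()].
#' @export
phantom_base_tissue <- function() {
  tissue_model(
    water_t1 = 1.8, water_t2 = 0.055,
    solute_pools = list(
      pool("amide", 3.5, t1 = 1.0, t2 = 0.010, exchange_rate = 200,
           volume_fraction = 0.003),
      pool("glu", 3.0, t1 = 1.0, t2 = 0.002, exchange_rate = 7000,
           volume_fraction = glu_conc_to_fraction(10)),
      pool("rnoe", -3.5, t1 = 1.0, t2 = 0.002, exchange_rate = 20,
           volume_fraction = 0.010)),
    semisolid = semisolid_pool(volume_fraction = 0.10, exchange_rate = 40))
}

#' Specify the digital multi-compound phantom
#'
#' A 5 x 5 array of circular vials varies the amide proton volume fraction
#' along one axis and the glutamate concentration along the other; the
#' array is replicated for each semisolid MT background fraction, yielding
#' `5 * 5 * 4 = 100` unique (f_amide, glu, f_ss) combinations by default.
#'
#' @param amide_fractions Five amide proton volume fractions (dimensionless;
#'   defaults span 0.09%-0.81%).
#' @param glu_concentrations Five glutamate concentrations in mM (defaults
#'   5-25 mM).
#' @param mt_fractions Semisolid MT background volume fractions (default 4
#'   values, 6%-24%).
#' @param image_size Square image edge in pixels.
#' @param vial_radius Vial radius in pixels.
#' @param base_tissue Tissue defaults for all non-varied parameters.
#' @return An object of class `cest_phantom_spec`.
#' @export
phantom_spec <- function(amide_fractions = seq(0.0009, 0.0081,
                                               length.out = 5),
                         glu_concentrations = seq(5, 25, length.out = 5),
                         mt_fractions = c(0.06, 0.12, 0.18, 0.24),
                         image_size = 64, vial_radius = 4,
                         base_tissue = phantom_base_tissue()) {
  stopifnot(inherits(base_tissue, "cest_tissue"))
  na <- length(amide_fractions); ng <- length(glu_concentrations)
  centers <- round(seq(from = image_size / (na + 1), by = image_size / (na + 1),
                       length.out = na))
  if (max(centers) + vial_radius > image_size ||
      min(centers) - vial_radius < 1)
    stop("vial geometry overflows the image bounds")
  ng <- length(glu_concentrations)
  centers_g <- if (ng == na) centers else
    round(seq(from = image_size / (ng + 1), by = image_size / (ng + 1),
              length.out = ng))
  if (max(centers_g) + vial_radius > image_size ||
      min(centers_g) - vial_radius < 1)
    stop("vial geometry overflows the image bounds")
  min_gap <- min(if (na > 1) diff(centers) else Inf,
                 if (ng > 1) diff(centers_g) else Inf)
  if (min_gap < 2 * vial_radius + 1)
    stop("vials overlap; reduce 'vial_radius' or enlarge 'image_size'")
  if (anyDuplicated(amide_fractions) || anyDuplicated(glu_concentrations) ||
      anyDuplicated(mt_fractions))
    stop("phantom parameter values must be distinct")
  structure(list(amide_fractions = amide_fractions,
                 glu_concentrations = glu_concentrations,
                 mt_fractions = mt_fractions, image_size = image_size,
                 vial_radius = vial_radius, centers = centers,
                 centers_g = centers_g, base_tissue = base_tissue),
            class = "cest_phantom_spec")
}

# Vial id image: 0 background, 1..(na*ng) row-major over (amide, glu).
.vial_id_map <- function(spec) {
  n <- spec$image_size
  id <- matrix(0L, n, n)
  na <- length(spec$amide_fractions); ng <- length(spec$glu_concentrations)
  xg <- matrix(seq_len(n), n, n); yg <- t(xg)
  k <- 0L
  centers_g <- spec$centers_g %||% spec$centers
  for (ia in seq_len(na)) for (ig in seq_len(ng)) {
    k <- k + 1L
    cx <- spec$centers[ia]; cy <- centers_g[ig]
    inside <- (xg - cx)^2 + (yg - cy)^2 <= spec$vial_radius^2
    id[inside] <- k
  }
  id
}

#' Synthesize the digital multi-compound phantom dataset
#'
#' For each semisolid MT background, every vial pixel's four MRF signal
#' trajectories are simulated from that vial's tissue model (piecewise-
#' constant ground truth), then white Gaussian noise with standard
#' deviation `noise_sigma * M0` is added independently to every entry of
#' every pixel trajectory. Background pixels carry zero signal and are
#' excluded from all statistics.
#'
#' @param spec A [phantom_spec()].
#' @param schedules Named list of the four MRF protocol schedules
#'   (`mt`, `rnoe`, `amide`, `glu`); defaults to [default_schedule()] for
#'   each target.
#' @param noise_sigma Noise standard deviation as a fraction of M0
#'   (default 0.01).
#' @param seed Integer seed controlling the noise draw.
#' @return An object of class `cest_phantom`: truth maps (per-pixel
#'   `f_ss`, `f_amide`, `glu_mM` arrays of dimension image x image x
#'   n-backgrounds), four trajectory stacks (image x image x 31 x
#'   n-backgrounds), constant `t1_map`/`t2_map`, the `vial_id` image, and
#'   the generation metadata.
#' @examples
#' \donttest{
#' ph <- make_digital_phantom(phantom_spec(image_size = 32, vial_radius = 2))
#' dim(ph$traj$mt)
#' }
#' @export
make_digital_phantom <- function(spec = phantom_spec(), schedules = NULL,
                                 noise_sigma = 0.01, seed = 0) {
  stopifnot(inherits(spec, "cest_phantom_spec"))
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (is.null(schedules))
    schedules <- lapply(stats::setNames(nm = c("mt", "rnoe", "amide", "glu")),
                        default_schedule)
  n <- spec$image_size
  nb <- length(spec$mt_fractions)
  na <- length(spec$amide_fractions); ng <- length(spec$glu_concentrations)
  nv <- na * ng
  vial_id <- .vial_id_map(spec)
  ne <- length(schedules[[1]]$entries)
  base <- spec$base_tissue
  # vial truth in row-major order over (amide, glu), matching .vial_id_map
  vial_amide <- rep(spec$amide_fractions, each = ng)
  vial_glu <- rep(spec$glu_concentrations, times = na)
  truth <- list(
    f_ss = array(0, c(n, n, nb)), f_amide = array(0, c(n, n, nb)),
    glu_mM = array(0, c(n, n, nb)))
  traj <- lapply(schedules, function(s) array(0, c(n, n, ne, nb)))
  lut <- function(vals) matrix(c(0, vals)[vial_id + 1L], n, n)
  for (ib in seq_len(nb)) {
    tissues <- lapply(seq_len(nv), function(v) {
      t_v <- base
      t_v$solute_pools$amide$volume_fraction <- vial_amide[v]
      t_v$solute_pools$glu$volume_fraction <-
        glu_conc_to_fraction(vial_glu[v])
      t_v$semisolid$volume_fraction <- spec$mt_fractions[ib]
      t_v
    })
    truth$f_ss[, , ib] <- lut(rep(spec$mt_fractions[ib], nv))
    truth$f_amide[, , ib] <- lut(vial_amide)
    truth$glu_mM[, , ib] <- lut(vial_glu)
    for (pn in names(schedules)) {
      sigs <- t(vapply(tissues, function(tt)
        simulate_trajectory(tt, schedules[[pn]])$values, numeric(ne)))
      for (e in seq_len(ne)) traj[[pn]][, , e, ib] <- lut(sigs[, e])
    }
  }
  if (noise_sigma > 0)
    traj <- with_local_seed(seed,
      lapply(traj, add_noise, sigma = noise_sigma, seed = NULL))
  t1_map <- matrix(base$water_t1, n, n); t1_map[vial_id == 0] <- 0
  t2_map <- matrix(base$water_t2, n, n); t2_map[vial_id == 0] <- 0
  structure(list(truth = truth, traj = traj, t1_map = t1_map,
                 t2_map = t2_map, vial_id = vial_id, spec = spec,
                 vial_amide = vial_amide, vial_glu = vial_glu,
                 noise_sigma = noise_sigma, seed = seed,
                 schedule_hash = vapply(schedules, schedule_hash,
                                        character(1))),
            class = "cest_phantom")
}

#' @export
print.cest_phantom <- function(x, ...) {
  cat(sprintf(
    "<cest_phantom> %dx%d px, %d vials x %d MT backgrounds (%d combinations), sigma = %g, seed = %d\n",
    nrow(x$vial_id), ncol(x$vial_id), length(x$vial_amide),
    length(x$spec$mt_fractions),
    length(x$vial_amide) * length(x$spec$mt_fractions), x$noise_sigma,
    x$seed))
  invisible(x)
}

#' Add white Gaussian noise to signal trajectories
#'
#' Adds independent zero-mean Gaussian noise with standard deviation
#' `sigma * M0` to every entry, where M0 is each trajectory's own
#' unsaturated (first) entry. Accepts a trajectory vector, a matrix of
#' row trajectories, or a pixel stack whose third dimension indexes the
#' schedule entries.
#'
#' @param x Trajectory container (vector, n x entries matrix, or array with
#'   entries along dimension 3).
#' @param sigma Noise standard deviation as a fraction of M0 (>= 0).
#' @param seed Optional integer seed (drawn from the current RNG stream when
#'   `NULL`).
#' @return Same shape as `x`.
#' @export
add_noise <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(x)
  draw <- function() {
    if (is.matrix(x)) {
      x + rnorm(length(x)) * sigma * x[, 1]
    } else if (is.array(x) && length(dim(x)) == 3) {
      d <- dim(x)  # H x W x entries, M0 in entry 1
      scale <- array(rep(x[, , 1], d[3]), d)
      x + array(rnorm(length(x)), d) * sigma * scale
    } else if (is.array(x) && length(dim(x)) == 4) {
      d <- dim(x)  # H x W x entries x backgrounds
      out <- x
      for (b in seq_len(d[4])) {
        scale <- array(rep(x[, , 1, b], d[3]), d[1:3])
        out[, , , b] <- x[, , , b] +
          array(rnorm(prod(d[1:3])), d[1:3]) * sigma * scale
      }
      out
    } else {
      x + rnorm(length(x)) * sigma * x[1]
    }
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
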