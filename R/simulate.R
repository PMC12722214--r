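#' Thermal-equilibrium magnetization state
#'
#' The state vector is ordered x then y then z for each free pool (water
#' first), followed by the semisolid longitudinal component when present.
#' At equilibrium every pool's z equals its volume fraction (water = 1).
#'
#' @param tissue A [tissue_model()].
#' @return Named numeric state vector.
#' @export
equilibrium_state <- function(tissue) {
  m <- .bm_equilibrium(.tissue_cpp(tissue))
  names(m) <- .state_names(tissue)
  m
}

.state_names <- function(tissue) {
  nm <- c("water", names(tissue$solute_pools))
  out <- c(paste0("x_", nm), paste0("y_", nm), paste0("z_", nm))
  if (!is.null(tissue$semisolid)) out <- c(out, "z_semisolid")
  out
}

#' Evolve a magnetization state through a saturation event
#'
#' Integrates the coupled Bloch-McConnell system (full transverse and
#' longitudinal dynamics for water and mobile solutes; longitudinal-only
#' semisolid pool saturated at rate \eqn{\pi\omega_1^2 g(\Delta\omega)})
#' for the event duration under continuous-wave irradiation.
#'
#' @param state Numeric state vector (see [equilibrium_state()]).
#' @param tissue A [tissue_model()].
#' @param event A [saturation_event()].
#' @param b0_field Static field in tesla.
#' @param method `"expm"` (default) propagates with the matrix exponential
#'   of the piecewise-constant generator; `"rk4"` uses fixed-step classical
#'   Runge-Kutta integration (an independent propagation route).
#' @param step Time step in seconds for `method = "rk4"`.
#' @return The evolved state vector.
#' @examples
#' t <- tissue_model(1.8, 0.06)
#' evolve_state(equilibrium_state(t), t, saturation_event(2, 3.5, 1))
#' @export
evolve_state <- function(state, tissue, event, b0_field = 7,
                         method = c("expm", "rk4"), step = 1e-5) {
  method <- match.arg(method)
  stopifnot(inherits(event, "cest_sat_event"))
  tc <- .tissue_cpp(tissue)
  out <- if (method == "expm")
    .bm_evolve(tc, as.numeric(state), event$b1_amplitude,
               event$frequency_offset, event$duration, b0_field)
  else
    .bm_evolve_rk4(tc, as.numeric(state), event$b1_amplitude,
                   event$frequency_offset, event$duration, b0_field, step)
  names(out) <- .state_names(tissue)
  out
}

#' Simulate an MRF signal trajectory
#'
#' Sequentially evolves the magnetization across the schedule entries with
#' carry-over between entries (the acquisition is non-steady-state). Per
#' entry the readout is idealized: the recorded signal is the water
#' longitudinal magnetization at the end of saturation weighted by
#' `exp(-TE / water_t2)`; the transverse magnetization is then spoiled, the
#' water longitudinal magnetization is consumed by an ideal 90-degree
#' excitation, and the system relaxes for the remainder of TR.
#'
#' @param tissue A [tissue_model()].
#' @param schedule A [acquisition_schedule()].
#' @return An object of class `cest_trajectory`: list with `values` (one
#'   non-negative signal per entry, the first corresponding to the M0 entry
#'   when the schedule starts unsaturated) and `schedule_id`.
#' @examples
#' sig <- simulate_trajectory(tissue_model(1.8, 0.06), default_schedule("mt"))
#' length(sig$values)
#' @export
simulate_trajectory <- function(tissue, schedule) {
  m <- .schedule_matrix(schedule)
  v <- .bm_trajectory(.tissue_cpp(tissue), m, schedule$b0_field)
  structure(list(values = as.numeric(v), schedule_id = schedule$id),
            class = "cest_trajectory")
}

#' @export
print.cest_trajectory <- function(x, ...) {
  cat(sprintf("<cest_trajectory> '%s': %d entries, M0 = %.4g\n",
              x$schedule_id, length(x$values), x$values[1]))
  invisible(x)
}

#' Simulate a Z-spectrum
#'
#' Runs a Z-spectrum protocol (see [zspectrum_schedule()]) and normalizes
#' each saturated signal by the unsaturated M0 signal,
#' \eqn{Z(\Delta\omega) = S_{sat}(\Delta\omega) / S_0}. Unlike the MRF
#' trajectory, every offset of a conventional Z-spectrum scan is treated
#' as an independent long-TR measurement: the magnetization starts from
#' thermal equilibrium at each entry, as assumed by the standard
#' Z-spectrum metrics.
#'
#' @param tissue A [tissue_model()].
#' @param protocol A schedule built by [zspectrum_schedule()] or
#'   [wassr_schedule()] (first entry must be the M0 acquisition).
#' @return A [zspectrum()] object with offsets in acquisition order.
#' @examples
#' z <- simulate_zspectrum(tissue_model(1.8, 0.06),
#'                         zspectrum_schedule(seq(2, -2, by = -0.5), b1 = 0.5))
#' @export
simulate_zspectrum <- function(tissue, protocol) {
  m <- .schedule_matrix(protocol)
  if (m[1, 1] != 0)
    stop("the protocol must start with an unsaturated M0 entry")
  tc <- .tissue_cpp(tissue)
  eq <- .bm_equilibrium(tc)
  izw <- 2 * (length(tissue$solute_pools) + 1) + 1
  zv <- vapply(seq_len(nrow(m))[-1], function(e) {
    st <- .bm_evolve(tc, eq, m[e, 2], m[e, 3], m[e, 4], protocol$b0_field)
    st[izw]
  }, numeric(1))
  zspectrum(offsets = m[-1, 3], z_values = pmin(pmax(zv, 0), 1),
            saturation_power = if (!is.null(attr(protocol, "b1")))
              attr(protocol, "b1") else m[2, 2],
            saturation_duration = if (!is.null(attr(protocol, "duration")))
              attr(protocol, "duration") else m[2, 4])
}
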