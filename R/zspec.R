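#' Construct a Z-spectrum
#'
#' A Z-spectrum pairs saturation frequency offsets (ppm from water) with
#' the normalized water signal \eqn{Z = S_{sat}/S_0}.
#'
#' @param offsets Offsets in ppm, strictly monotone (default acquisition
#'   order is 7 down to -7 ppm).
#' @param z_values Normalized signals, expected in `[0, 1.05]` (small
#'   tolerance for noise).
#' @param saturation_power Saturation amplitude in microtesla (metadata).
#' @param saturation_duration Saturation duration in seconds (metadata).
#' @return An object of class `cest_zspectrum`.
#' @export
zspectrum <- function(offsets, z_values, saturation_power = NA_real_,
                      saturation_duration = NA_real_) {
  offsets <- as.numeric(offsets); z_values <- as.numeric(z_values)
  if (length(offsets) != length(z_values))
    stop("'offsets' and 'z_values' must have equal length")
  d <- diff(offsets)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("'offsets' must be strictly monotone")
  zr <- range(z_values, na.rm = TRUE)
  if (zr[1] < -0.05 || zr[2] > 1.05)
    stop("z values outside [0, 1.05]: not a normalized Z-spectrum")
  structure(list(offsets = offsets, z_values = z_values,
                 saturation_power = saturation_power,
                 saturation_duration = saturation_duration),
            class = "cest_zspectrum")
}

#' @export
print.cest_zspectrum <- function(x, ...) {
  cat(sprintf("<cest_zspectrum> %d offsets in [%g, %g] ppm, B1 = %g uT, t_sat = %g s\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              x$saturation_power, x$saturation_duration))
  invisible(x)
}

#' @export
plot.cest_zspectrum <- function(x, ...) {
  graphics::plot(x$offsets, x$z_values, type = "b", xlim = rev(range(x$offsets)),
                 xlab = "offset [ppm]", ylab = "Z", ...)
  invisible(x)
}

# Cubic-spline interpolation of Z at arbitrary offsets.
.z_interp <- function(z, xout) {
  stopifnot(inherits(z, "cest_zspectrum"))
  ok <- !is.na(z$z_values)
  spline(z$offsets[ok], z$z_values[ok], xout = xout, method = "fmm")$y
}

#' Locate the per-pixel B0 shift with WASSR
#'
#' Interpolates each low-power Z-spectrum to 0.001-ppm resolution with a
#' cubic spline and returns the offset of its minimum (the apparent water
#' center). Minima on the sweep boundary are flagged as unreliable.
#'
#' @param z A `cest_zspectrum` over roughly +/- 1 ppm, or a matrix with
#'   one spectrum per row.
#' @param offsets Offsets in ppm when `z` is a matrix.
#' @param resolution Interpolation step in ppm (default 0.001).
#' @return For a single spectrum, a list with `shift` (ppm) and `flagged`;
#'   for a matrix, a list of vectors.
#' @examples
#' t <- tissue_model(1.8, 0.06, b0_shift = 0.1)
#' wassr_b0(simulate_zspectrum(t, wassr_schedule()))$shift
#' @export
wassr_b0 <- function(z, offsets = NULL, resolution = 0.001) {
  one <- function(off, zv) {
    ok <- !is.na(zv)
    fine <- seq(min(off[ok]), max(off[ok]), by = resolution)
    zi <- spline(off[ok], zv[ok], xout = fine, method = "fmm")$y
    i <- which.min(zi)
    list(shift = fine[i], flagged = i == 1L || i == length(fine))
  }
  if (inherits(z, "cest_zspectrum"))
    return(one(z$offsets, z$z_values))
  if (is.matrix(z)) {
    if (is.null(offsets)) stop("'offsets' required for matrix input")
    res <- apply(z, 1, function(r) one(offsets, r))
    return(list(shift = vapply(res, `[[`, numeric(1), "shift"),
                flagged = vapply(res, `[[`, logical(1), "flagged")))
  }
  stop("'z' must be a cest_zspectrum or a matrix of spectra")
}

#' Correct a Z-spectrum for a B0 shift
#'
#' Re-samples the spectrum at `offsets + shift` with a cubic spline so
#' that spectral features re-align with their nominal offsets. Offsets
#' falling outside the acquired range are marked missing (`NA`).
#'
#' @param z A `cest_zspectrum`.
#' @param shift Field shift in ppm (|shift| <= 1, the WASSR sweep range).
#' @return A corrected `cest_zspectrum`.
#' @export
b0_correct <- function(z, shift) {
  stopifnot(inherits(z, "cest_zspectrum"))
  if (!is.finite(shift) || abs(shift) > 1)
    stop("'shift' must be within +/- 1 ppm")
  if (shift == 0) return(z)
  xout <- z$offsets + shift
  zi <- .z_interp(z, xout)
  zi[xout < min(z$offsets) | xout > max(z$offsets)] <- NA_real_
  zspectrum(z$offsets, pmin(pmax(zi, -0.05), 1.05),
            z$saturation_power, z$saturation_duration)
}

#' Cubic-spline smoothing of a Z-spectrum
#'
#' @param z A `cest_zspectrum`.
#' @param smoothing Smoothing parameter (`spar` of
#'   [stats::smooth.spline()]); `0` returns the input unchanged at the
#'   nodes and `NULL` (the default) selects the parameter by generalized
#'   cross-validation.
#' @return A smoothed `cest_zspectrum` (fitted values clamped to the input
#'   range).
#' @export
smooth_zspectrum <- function(z, smoothing = NULL) {
  stopifnot(inherits(z, "cest_zspectrum"))
  if (!is.null(smoothing) && smoothing < 0)
    stop("'smoothing' must be >= 0")
  if (!is.null(smoothing) && smoothing == 0) return(z)
  ok <- !is.na(z$z_values)
  fit <- if (is.null(smoothing))
    smooth.spline(z$offsets[ok], z$z_values[ok], cv = FALSE)
  else smooth.spline(z$offsets[ok], z$z_values[ok], spar = smoothing)
  out <- z$z_values
  out[ok] <- predict(fit, z$offsets[ok])$y
  out <- pmin(pmax(out, min(z$z_values, na.rm = TRUE)),
              max(z$z_values, na.rm = TRUE))
  zspectrum(z$offsets, out, z$saturation_power, z$saturation_duration)
}

#' Magnetization transfer ratio and asymmetry
#'
#' `mtr` computes \eqn{MTR(\Delta\omega) = 1 - S_{sat}(\Delta\omega)/S_0};
#' `mtr_asym` computes \eqn{(S_{sat}(-\omega) - S_{sat}(+\omega))/S_0}.
#' Z is spline-interpolated to the requested offsets.
#'
#' @param z A `cest_zspectrum`.
#' @param offset Offset(s) in ppm.
#' @return Dimensionless metric value(s).
#' @export
mtr <- function(z, offset) 1 - .z_interp(z, offset)

#' @rdname mtr
#' @export
mtr_asym <- function(z, offset) .z_interp(z, -offset) - .z_interp(z, offset)

#' Observed saturation-transfer difference
#'
#' \eqn{\Delta ST(\pm 3.5\,ppm) = Z(7\,ppm) - Z(\pm 3.5\,ppm)}.
#'
#' @param z A `cest_zspectrum`.
#' @param offset Target offset in ppm (typically +3.5 or -3.5).
#' @param reference_offset Reference offset (default 7 ppm).
#' @return Dimensionless difference (may be negative).
#' @export
delta_st <- function(z, offset, reference_offset = 7) {
  .z_interp(z, reference_offset) - .z_interp(z, offset)
}

#' Glutamate-weighted CEST contrast
#'
#' \eqn{GluCEST(\%) = 100 (M_{sat}(-3) - M_{sat}(+3)) / M_{sat}(-3)},
#' evaluated on a high-power (5.9 uT) Z-spectrum.
#'
#' @param z A `cest_zspectrum`.
#' @return Percent contrast.
#' @export
glucest <- function(z) {
  m_neg <- .z_interp(z, -3); m_pos <- .z_interp(z, 3)
  if (m_neg == 0) stop("M_sat(-3 ppm) is zero; GluCEST undefined")
  100 * (m_neg - m_pos) / m_neg
}

#' Amine/amide concentration-independent detection (AACID)
#'
#' \eqn{AACID = M_{sat}(3.5) (M_{sat}(6) - M_{sat}(2.75)) /
#' (M_{sat}(2.75) (M_{sat}(6) - M_{sat}(3.5)))}, a pH surrogate evaluated
#' on a 1.5 uT Z-spectrum. Being a ratio of ratios it is invariant to
#' overall scaling of the spectrum.
#'
#' @param z A `cest_zspectrum`.
#' @return Dimensionless value.
#' @export
aacid <- function(z) {
  m35 <- .z_interp(z, 3.5); m275 <- .z_interp(z, 2.75)
  m6 <- .z_interp(z, 6)
  den <- m275 * (m6 - m35)
  if (den == 0) stop("AACID denominator is zero")
  m35 * (m6 - m275) / den
}

#' Default five-pool Lorentzian decomposition model
#'
#' Start values and bounds for water, semisolid MT, amide, rNOE, and
#' amine pools (centers 0, -2.3, 3.5, -3.5, 3 ppm).
#'
#' @return Data frame with one row per pool: start values and bounds for
#'   amplitude, full width at half maximum (ppm) and center (ppm).
#' @export
lorentzian_pool_defaults <- function() {
  data.frame(
    name = c("water", "mt", "amide", "rnoe", "amine"),
    amp = c(0.8, 0.1, 0.02, 0.02, 0.01),
    amp_lo = 0,
    amp_hi = c(1, 0.9, 0.4, 0.4, 0.4),
    width = c(2.0, 25, 1.5, 3, 2),
    width_lo = c(0.3, 10, 0.4, 0.5, 0.4),
    width_hi = c(8, 100, 6, 8, 6),
    center = c(0, -2.3, 3.5, -3.5, 3),
    center_lo = c(-0.5, -3.5, 3.2, -4.0, 2.7),
    center_hi = c(0.5, -1.0, 3.8, -3.0, 3.3))
}

.lorentz <- function(x, amp, width, center) {
  amp * (width^2 / 4) / (width^2 / 4 + (x - center)^2)
}

#' Fit a multipool Lorentzian model to a Z-spectrum
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' \eqn{Z(\omega) = 1 - \sum_i L_i(\omega)} where each pool contributes a
#' Lorentzian line with amplitude, width, and center. Start values are
#' fixed by the pool table, so the fit is deterministic. The labeled
#' spectrum `Z_lab` is the complete fit; the reference `Z_ref` for a pool
#' omits that pool's Lorentzian.
#'
#' @param z A B0-corrected `cest_zspectrum`.
#' @param pools Pool table as in [lorentzian_pool_defaults()] (any subset
#'   or custom pools).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `cest_lorentzian_fit`: `pools` (fitted
#'   amplitude/width/center per pool), `residual` (root-mean-square), and
#'   `converged`.
#' @export
fit_multipool_lorentzian <- function(z, pools = lorentzian_pool_defaults(),
                                     max_iter = 200) {
  stopifnot(inherits(z, "cest_zspectrum"))
  ok <- !is.na(z$z_values)
  x <- z$offsets[ok]; y <- z$z_values[ok]
  np <- nrow(pools)
  par0 <- c(pools$amp, pools$width, pools$center)
  lower <- c(pools$amp_lo, pools$width_lo, pools$center_lo)
  upper <- c(pools$amp_hi, pools$width_hi, pools$center_hi)
  model <- function(par, xx) {
    zz <- rep(1, length(xx))
    for (i in seq_len(np))
      zz <- zz - .lorentz(xx, par[i], par[np + i], par[2 * np + i])
    zz
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(par) model(par, x) - y,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  par <- fit$par
  out <- data.frame(name = pools$name, amplitude = par[seq_len(np)],
                    width = par[np + seq_len(np)],
                    center = par[2 * np + seq_len(np)])
  structure(list(pools = out, residual = sqrt(mean(fit$fvec^2)),
                 converged = fit$info %in% 1:4, info = fit$info,
                 offsets = z$offsets),
            class = "cest_lorentzian_fit")
}

#' @export
print.cest_lorentzian_fit <- function(x, ...) {
  cat(sprintf("<cest_lorentzian_fit> %d pools, RMS residual %.3e%s\n",
              nrow(x$pools), x$residual,
              if (x$converged) "" else " (NOT converged)"))
  print(x$pools, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Labeled and reference spectra of a Lorentzian decomposition
#'
#' `z_lab` evaluates the complete fit \eqn{1 - \sum_i L_i};
#' `z_ref` omits the target pool's contribution.
#'
#' @param fit A `cest_lorentzian_fit`.
#' @param offsets Offsets in ppm.
#' @param pool Pool name to omit (for `z_ref`).
#' @return Numeric vector of model Z values.
#' @export
z_lab <- function(fit, offsets) .z_model(fit, offsets, exclude = NULL)

#' @rdname z_lab
#' @export
z_ref <- function(fit, offsets, pool) .z_model(fit, offsets, exclude = pool)

.z_model <- function(fit, offsets, exclude = NULL) {
  stopifnot(inherits(fit, "cest_lorentzian_fit"))
  if (!is.null(exclude) && !exclude %in% fit$pools$name)
    stop("unknown pool '", exclude, "'")
  zz <- rep(1, length(offsets))
  for (i in seq_len(nrow(fit$pools))) {
    if (!is.null(exclude) && fit$pools$name[i] == exclude) next
    zz <- zz - .lorentz(offsets, fit$pools$amplitude[i],
                        fit$pools$width[i], fit$pools$center[i])
  }
  zz
}

#' Lorentzian-difference exchange metric MTR_Rex
#'
#' \eqn{MTR_{Rex} = 1/Z_{lab} - 1/Z_{ref}}, the inverse-Z difference
#' between the full decomposition and the reference spectrum without the
#' target pool. It is antisymmetric under swapping the two spectra, zero
#' when the pool amplitude vanishes, and non-negative whenever
#' `z_ref >= z_lab > 0`.
#'
#' @param x A `cest_lorentzian_fit`, or the labeled Z value(s) directly.
#' @param ... Method arguments.
#' @return Metric value(s), units of inverse Z (dimensionless).
#' @examples
#' mtr_rex(0.5, 0.8)   # 0.75
#' @export
mtr_rex <- function(x, ...) UseMethod("mtr_rex")

#' @rdname mtr_rex
#' @param z_ref_values Reference Z value(s) (for the default method).
#' @export
mtr_rex.default <- function(x, z_ref_values, ...) {
  if (any(x <= 0) || any(z_ref_values <= 0))
    stop("Z values must be positive")
  1 / x - 1 / z_ref_values
}

#' @rdname mtr_rex
#' @param pool Target pool name.
#' @param offset Evaluation offset in ppm (defaults to the pool's fitted
#'   center).
#' @export
mtr_rex.cest_lorentzian_fit <- function(x, pool, offset = NULL, ...) {
  if (is.null(offset))
    offset <- x$pools$center[match(pool, x$pools$name)]
  mtr_rex.default(z_lab(x, offset), z_ref(x, offset, pool))
}

#' Apparent exchange-dependent relaxation
#'
#' \eqn{AREX = MTR_{Rex} / T_1}: the inverse-Z exchange metric
#' compensated for the water longitudinal relaxation time.
#'
#' @param mtr_rex_value MTR_Rex value(s).
#' @param t1 Water T1 in seconds (> 0).
#' @return Rate in 1/s.
#' @export
arex <- function(mtr_rex_value, t1) {
  if (any(t1 <= 0)) stop("'t1' must be positive")
  mtr_rex_value / t1
}
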