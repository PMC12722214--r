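#' Define a continuous-wave saturation event
#'
#' @param b1_amplitude Saturation amplitude in microtesla (>= 0).
#' @param frequency_offset Saturation frequency offset in ppm from water.
#' @param duration Saturation duration in seconds (> 0).
#' @param shape Pulse shape; only `"continuous_wave"` is currently
#'   implemented (the enum is extensible).
#' @return An object of class `cest_sat_event`.
#' @export
saturation_event <- function(b1_amplitude, frequency_offset, duration,
                             shape = "continuous_wave") {
  shape <- match.arg(shape, "continuous_wave")
  if (!is.finite(b1_amplitude) || b1_amplitude < 0)
    stop("'b1_amplitude' must be >= 0")
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be > 0")
  if (!is.finite(frequency_offset)) stop("'frequency_offset' must be finite")
  structure(list(b1_amplitude = b1_amplitude,
                 frequency_offset = frequency_offset,
                 duration = duration, shape = shape),
            class = "cest_sat_event")
}

#' Define one acquisition entry (saturation + readout)
#'
#' @param saturation A [saturation_event()], or `NULL` for an unsaturated M0
#'   acquisition.
#' @param tr Repetition time in seconds; must exceed the saturation duration
#'   plus `te`.
#' @param te Echo time in seconds.
#' @param excitation_flip Excitation flip angle in degrees (the readout model
#'   is an ideal 90-degree excitation with perfect spoiling).
#' @return An object of class `cest_entry`.
#' @export
schedule_entry <- function(saturation = NULL, tr, te = 0.020,
                           excitation_flip = 90) {
  if (!is.null(saturation) && !inherits(saturation, "cest_sat_event"))
    stop("'saturation' must be a cest_sat_event or NULL")
  dur <- if (is.null(saturation)) 0 else saturation$duration
  if (!is.finite(tr) || tr <= dur + te)
    stop("'tr' must exceed the saturation duration plus 'te'")
  structure(list(saturation = saturation, tr = tr, te = te,
                 excitation_flip = excitation_flip),
            class = "cest_entry")
}

#' Assemble an acquisition schedule
#'
#' An ordered list of entries defining one MRF protocol or one Z-spectrum
#' scan. MRF protocols consist of exactly 31 entries, the first being an
#' unsaturated M0 entry at TR 15 s / TE 20 ms.
#'
#' @param entries List of [schedule_entry()] objects.
#' @param b0_field Static field strength in tesla (default 7).
#' @param id Optional schedule label.
#' @return An object of class `cest_schedule`.
#' @export
acquisition_schedule <- function(entries, b0_field = 7, id = "schedule") {
  if (!is.list(entries) ||
      !all(vapply(entries, inherits, logical(1), "cest_entry")))
    stop("'entries' must be a list of cest_entry objects")
  if (b0_field <= 0) stop("'b0_field' must be positive")
  structure(list(entries = entries, b0_field = b0_field, id = id),
            class = "cest_schedule")
}

#' @export
print.cest_schedule <- function(x, ...) {
  m <- .schedule_matrix(x)
  cat(sprintf("<cest_schedule> '%s': %d entries (%d saturated), B0 = %g T, total %.1f s\n",
              x$id, nrow(m), sum(m[, 1] > 0), x$b0_field, sum(m[, 5])))
  invisible(x)
}

#' Total duration of a schedule in seconds
#' @param schedule A [acquisition_schedule()].
#' @export
schedule_duration <- function(schedule) {
  sum(vapply(schedule$entries, `[[`, numeric(1), "tr"))
}

# Columns: has_sat, b1_uT, offset_ppm, dur_s, tr_s, te_s
.schedule_matrix <- function(schedule) {
  stopifnot(inherits(schedule, "cest_schedule"))
  t(vapply(schedule$entries, function(e) {
    if (is.null(e$saturation)) c(0, 0, 0, 0, e$tr, e$te)
    else c(1, e$saturation$b1_amplitude, e$saturation$frequency_offset,
           e$saturation$duration, e$tr, e$te)
  }, numeric(6)))
}

# Stable content hash of a schedule (used to guard model/schedule pairing).
schedule_hash <- function(schedule) {
  m <- .schedule_matrix(schedule)
  txt <- paste(c(format(m, digits = 12), schedule$b0_field), collapse = ",")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Default MRF protocol schedules
#'
#' Builds the 31-entry fingerprinting schedule for one of the four encoding
#' targets. The first entry is an unsaturated M0 acquisition (TR 15 s,
#' TE 20 ms); the remaining 30 entries apply continuous-wave saturation with
#' pseudo-randomly varied amplitude (and, for the semisolid MT protocol,
#' offset) in a target-appropriate range:
#' \describe{
#'   \item{mt}{offsets 6-14 ppm, B1 0-6 uT, 2.5 s saturation (a spectral
#'     range where no mobile metabolite is visible; the broad pool
#'     saturates slowly)}
#'   \item{rnoe}{-3.5 ppm, low powers 0.3-2 uT, 2.5 s saturation (slow
#'     exchange needs long low-power labeling)}
#'   \item{amide}{+3.5 ppm, 0.3-4 uT, 1.5 s saturation}
#'   \item{glu}{offsets alternating +(2-3) and -(2-3) ppm, high powers
#'     2-7 uT, 0.3 s saturation — for the fast-exchanging, heavily
#'     spill-over-shadowed amine pool the transient short-saturation
#'     regime carries several-fold more concentration contrast than
#'     saturation to steady state; exchange broadening makes the amine
#'     response insensitive to sub-ppm carrier changes while the amide
#'     response is not, and the mirrored negative-offset entries embed a
#'     symmetric water/semisolid reference into the fingerprint (the
#'     asymmetry principle of glutamate-weighted CEST), decoupling the
#'     amine signal from the dominant background pools}
#' }
#' Saturated entries use TE 20 ms and a TR (3.6-3.8 s) that places every
#' protocol inside the 120-135 s scan-time envelope. Generation is seeded
#' and reproducible.
#'
#' @param target One of `"mt"`, `"rnoe"`, `"amide"`, `"glu"`.
#' @param seed Integer seed for the pseudo-random B1/offset draws.
#' @param b0_field Static field in tesla.
#' @return A 31-entry [acquisition_schedule()].
#' @examples
#' sched <- default_schedule("mt")
#' schedule_duration(sched)
#' @export
default_schedule <- function(target = c("mt", "rnoe", "amide", "glu"),
                             seed = 1, b0_field = 7) {
  target <- match.arg(target)
  n_sat <- 30
  rng <- with_local_seed(seed + match(target, c("mt", "rnoe", "amide", "glu")),
    {
      b1 <- switch(target,
        mt = runif(n_sat, 0, 6),
        rnoe = runif(n_sat, 0.3, 2),
        amide = runif(n_sat, 0.3, 4),
        glu = runif(n_sat, 2, 7))
      off <- switch(target,
        mt = runif(n_sat, 6, 14),
        rnoe = rep(-3.5, n_sat),
        amide = rep(3.5, n_sat),
        glu = runif(n_sat, 2, 3) * rep(c(1, -1), length.out = n_sat))
      list(b1 = b1, off = off)
    })
  dur <- switch(target, mt = 2.5, rnoe = 2.5, amide = 1.5, glu = 0.3)
  tr <- switch(target, mt = 3.8, rnoe = 3.8, amide = 3.7, glu = 3.6)
  entries <- c(
    list(schedule_entry(NULL, tr = 15, te = 0.020)),
    lapply(seq_len(n_sat), function(i)
      schedule_entry(saturation_event(rng$b1[i], rng$off[i], dur),
                     tr = tr, te = 0.020)))
  acquisition_schedule(entries, b0_field = b0_field,
                       id = paste0("mrf_", target))
}

#' Z-spectrum and WASSR acquisition protocols
#'
#' `zspectrum_schedule` sweeps the saturation offset (default 7 to -7 ppm)
#' at a fixed power, preceded by an unsaturated M0 entry.
#' `wassr_schedule` is the low-power variant used for water saturation shift
#' referencing (0.3 uT, 3 s saturation, -1 to 1 ppm in 0.1 ppm steps).
#'
#' @param offsets Saturation offsets in ppm, in acquisition order.
#' @param b1 Saturation amplitude in microtesla.
#' @param duration Saturation duration in seconds.
#' @param tr,te Repetition and echo times in seconds.
#' @param b0_field Static field in tesla.
#' @return A [acquisition_schedule()] whose first entry is the M0
#'   acquisition.
#' @export
zspectrum_schedule <- function(offsets = seq(7, -7, by = -0.25), b1 = 0.7,
                               duration = 3, tr = 8, te = 0.020,
                               b0_field = 7) {
  entries <- c(
    list(schedule_entry(NULL, tr = 15, te = te)),
    lapply(offsets, function(o)
      schedule_entry(saturation_event(b1, o, duration), tr = tr, te = te)))
  sch <- acquisition_schedule(entries, b0_field = b0_field, id = "zspectrum")
  attr(sch, "offsets") <- offsets
  attr(sch, "b1") <- b1
  attr(sch, "duration") <- duration
  sch
}

#' @rdname zspectrum_schedule
#' @export
wassr_schedule <- function(offsets = seq(-1, 1, by = 0.1), b1 = 0.3,
                           duration = 3, tr = 8, te = 0.020, b0_field = 7) {
  sch <- zspectrum_schedule(offsets, b1, duration, tr, te, b0_field)
  sch$id <- "wassr"
  sch
}

#' Read or write a schedule as YAML
#'
#' Schedules are stored as a list of per-entry records
#' `{b1_uT, offset_ppm, sat_duration_s, tr_s, te_s}` (saturation fields
#' absent for M0 entries) plus the field strength.
#'
#' @param schedule A [acquisition_schedule()].
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "cest_schedule"))
  entries <- lapply(schedule$entries, function(e) {
    rec <- list(tr_s = e$tr, te_s = e$te)
    if (!is.null(e$saturation))
      rec <- c(list(b1_uT = e$saturation$b1_amplitude,
                    offset_ppm = e$saturation$frequency_offset,
                    sat_duration_s = e$saturation$duration), rec)
    rec
  })
  yaml::write_yaml(list(id = schedule$id, b0_field = schedule$b0_field,
                        entries = entries), path, precision = 15)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- yaml::read_yaml(path)
  entries <- lapply(x$entries, function(e) {
    sat <- if (!is.null(e$b1_uT))
      saturation_event(e$b1_uT, e$offset_ppm, e$sat_duration_s)
    schedule_entry(sat, tr = e$tr_s, te = e$te_s)
  })
  acquisition_schedule(entries, b0_field = x$b0_field,
                       id = x$id %||% "schedule")
}
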