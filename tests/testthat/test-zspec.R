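# Simple spectra built from explicit values at the offsets of interest.
flat_z <- function(level = 1, offsets = seq(7, -7, by = -0.5)) {
  zspectrum(offsets, rep(level, length(offsets)))
}

dip_z <- function(vals, offsets = seq(7, -7, by = -0.5)) {
  # vals: named list offset -> z; others default to 0.9
  z <- rep(0.9, length(offsets))
  for (nm in names(vals)) z[offsets == as.numeric(nm)] <- vals[[nm]]
  zspectrum(offsets, z)
}

test_that("MTR and MTR asymmetry reproduce their hand-computed examples", {
  expect_equal(mtr(flat_z(1), 3.5), 0)
  expect_equal(mtr(flat_z(0), 3.5), 1)
  expect_equal(mtr(dip_z(list(`3.5` = 0.7)), 3.5), 0.3)
  expect_equal(mtr_asym(dip_z(list(`3.5` = 0.7, `-3.5` = 0.8)), 3.5), 0.1)
  expect_equal(mtr_asym(flat_z(0.8), 2), 0)
  expect_equal(mtr_asym(dip_z(list(`2` = 0.5)), 0), 0)
})

test_that("MTR_asym equals MTR(+w) - MTR(-w) identically on random spectra", {
  set.seed(11)
  for (i in 1:10) {
    z <- zspectrum(seq(7, -7, by = -0.25),
                   runif(57, 0.3, 1))
    w <- runif(5, 0, 6.5)
    expect_equal(mtr_asym(z, w), mtr(z, w) - mtr(z, -w), tolerance = 1e-12)
  }
})

test_that("delta-ST examples and sign behavior", {
  z <- dip_z(list(`7` = 0.9, `-3.5` = 0.75))
  expect_equal(delta_st(z, -3.5), 0.15)
  expect_equal(delta_st(flat_z(0.8), 3.5), 0)
  z2 <- dip_z(list(`7` = 0.7, `3.5` = 0.9))
  expect_lt(delta_st(z2, 3.5), 0)
})

test_that("GluCEST matches its definition and flags division by zero", {
  z <- dip_z(list(`-3` = 0.8, `3` = 0.6))
  expect_equal(glucest(z), 25)
  expect_equal(glucest(flat_z(0.9)), 0)
  expect_error(glucest(dip_z(list(`-3` = 0))), "zero")
})

test_that("AACID matches its definition and is scale invariant", {
  z <- zspectrum(c(7, 6, 3.5, 2.75, -7), c(0.9, 0.9, 0.5, 0.6, 0.9))
  expect_equal(aacid(z), 0.5 * 0.3 / (0.6 * 0.4))
  # equal amine/amide saturation collapses the expression to 1
  z_eq <- zspectrum(c(7, 6, 3.5, 2.75, -7), c(0.9, 0.9, 0.55, 0.55, 0.9))
  expect_equal(aacid(z_eq), 1)
  expect_error(aacid(zspectrum(c(7, 6, 3.5, 2.75, -7),
                               c(0.9, 0.5, 0.5, 0.7, 0.9))),
               "zero")
  set.seed(4)
  off <- seq(7, -7, by = -0.25)
  zv <- runif(length(off), 0.5, 1)
  for (s in c(0.5, 0.9)) {
    expect_equal(aacid(zspectrum(off, zv * s)),
                 aacid(zspectrum(off, zv)), tolerance = 1e-12)
  }
})

test_that("WASSR recovers a constructed shift and flags degenerate sweeps", {
  direct <- function(x, c0) 1 - 0.6 / (1 + ((x - c0) / 0.4)^2)
  off <- seq(-1, 1, by = 0.1)
  w <- wassr_b0(zspectrum(off, direct(off, 0)))
  expect_equal(w$shift, 0, tolerance = 1e-3)
  w <- wassr_b0(zspectrum(off, direct(off, 0.1)))
  expect_equal(w$shift, 0.1, tolerance = 1e-3)
  expect_false(w$flagged)
  w <- wassr_b0(zspectrum(off, seq(0.3, 0.9, length.out = length(off))))
  expect_true(w$flagged)
})

test_that("B0 correction re-aligns a shifted spectrum", {
  direct <- function(x, c0) 1 - 0.6 / (1 + ((x - c0) / 0.6)^2)
  off <- seq(3, -3, by = -0.1)
  z0 <- zspectrum(off, direct(off, 0))
  zs <- zspectrum(off, direct(off, 0.3))
  expect_identical(b0_correct(zs, 0), zs)
  zc <- b0_correct(zs, 0.3)
  inner <- abs(off) <= 2
  expect_lt(max(abs(zc$z_values[inner] - z0$z_values[inner])), 1e-3)
  expect_error(b0_correct(zs, 1.5), "1 ppm")
})

test_that("spline smoothing reduces noise and preserves the Z range", {
  direct <- function(x) 1 - 0.5 / (1 + (x / 1.2)^2)
  off <- seq(7, -7, by = -0.25)
  truth <- direct(off)
  set.seed(2)
  noisy <- zspectrum(off, pmin(pmax(truth + rnorm(length(off), 0, 0.01),
                                    0), 1))
  expect_identical(smooth_zspectrum(noisy, 0), noisy)
  sm <- smooth_zspectrum(noisy)  # GCV-selected smoothing
  expect_lt(sd(sm$z_values - truth), sd(noisy$z_values - truth))
  expect_gte(min(sm$z_values), min(noisy$z_values))
  expect_lte(max(sm$z_values), max(noisy$z_values))
})

test_that("the Lorentzian decomposition recovers known pools", {
  off <- seq(7, -7, by = -0.1)
  pools <- data.frame(name = c("water", "amide"),
                      amp = c(0.7, 0.08), amp_lo = 0, amp_hi = c(1, 0.4),
                      width = c(2.4, 1.1), width_lo = c(0.3, 0.4),
                      width_hi = c(8, 6),
                      center = c(0, 3.5), center_lo = c(-0.5, 3.2),
                      center_hi = c(0.5, 3.8))
  zv <- 1 - .lorentz(off, 0.72, 2.1, 0.05) - .lorentz(off, 0.06, 1.3, 3.45)
  fit <- fit_multipool_lorentzian(zspectrum(off, zv), pools)
  expect_true(fit$converged)
  est <- fit$pools
  expect_equal(est$center[est$name == "water"], 0.05, tolerance = 0.01)
  expect_equal(est$center[est$name == "amide"], 3.45, tolerance = 0.01 * 3.45)
  expect_equal(est$width[est$name == "water"], 2.1, tolerance = 0.01 * 2.1)
  expect_equal(est$width[est$name == "amide"], 1.3, tolerance = 0.01 * 1.3)
  expect_equal(est$amplitude, c(0.72, 0.06), tolerance = 0.01)
})

test_that("a flat spectrum yields vanishing non-water amplitudes", {
  off <- seq(7, -7, by = -0.25)
  fit <- fit_multipool_lorentzian(flat_z(1, off))
  amps <- fit$pools$amplitude[fit$pools$name != "water"]
  expect_true(all(amps <= 1e-6))
})

test_that("amplitudes are recovered within tolerance under noise", {
  off <- seq(7, -7, by = -0.1)
  zv <- 1 - .lorentz(off, 0.72, 2.1, 0) - .lorentz(off, 0.08, 1.5, 3.5)
  set.seed(9)
  zn <- zv + rnorm(length(off), 0, 0.005)
  pools <- data.frame(name = c("water", "amide"),
                      amp = c(0.7, 0.05), amp_lo = 0, amp_hi = c(1, 0.4),
                      width = c(2.4, 1.2), width_lo = c(0.3, 0.4),
                      width_hi = c(8, 6),
                      center = c(0, 3.5), center_lo = c(-0.5, 3.2),
                      center_hi = c(0.5, 3.8))
  fit <- fit_multipool_lorentzian(zspectrum(off, pmin(pmax(zn, 0), 1.05)),
                                  pools)
  expect_equal(fit$pools$amplitude[2], 0.08, tolerance = 0.2)
})

test_that("MTR_Rex and AREX follow their closed forms", {
  expect_equal(mtr_rex(0.5, 0.8), 0.75)
  expect_equal(mtr_rex(0.8, 0.8), 0)
  expect_equal(mtr_rex(0.8, 0.5), -mtr_rex(0.5, 0.8))
  expect_error(mtr_rex(0, 0.5), "positive")
  expect_equal(arex(0.75, 1.5), 0.5)
  expect_equal(arex(0, 2), 0)
  expect_error(arex(0.5, 0), "positive")
  # zero-amplitude pool contributes nothing
  off <- seq(7, -7, by = -0.25)
  fit <- fit_multipool_lorentzian(flat_z(1, off))
  expect_lt(abs(mtr_rex(fit, "amide")), 1e-5)
})

test_that("MTR_Rex is non-negative when the reference exceeds the label", {
  set.seed(3)
  zl <- runif(20, 0.2, 0.8)
  zr <- zl + runif(20, 0, 0.2)
  expect_true(all(mtr_rex(zl, zr) >= 0))
})

test_that("amide CEST metrics increase monotonically with the volume fraction", {
  off <- seq(7, -7, by = -0.25)
  pools <- lorentzian_pool_defaults()[c(1, 3), ]
  vals <- lapply(c(0.002, 0.005, 0.009), function(f) {
    tt <- tissue_model(1.8, 0.055,
                       list(pool("amide", 3.5, 1, 0.01, 120, f)))
    z <- simulate_zspectrum(tt, zspectrum_schedule(off, b1 = 0.9,
                                                   duration = 4))
    fit <- fit_multipool_lorentzian(z, pools)
    mr <- mtr_rex(fit, "amide", 3.5)
    c(mtr = mtr(z, 3.5), mtr_rex = mr, arex = arex(mr, 1.8))
  })
  m <- do.call(rbind, vals)
  expect_true(all(diff(m[, "mtr"]) > 0))
  expect_true(all(diff(m[, "mtr_rex"]) > 0))
  expect_true(all(diff(m[, "arex"]) > 0))
})
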