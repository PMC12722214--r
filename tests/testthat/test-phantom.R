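# A small, fast phantom used across tests.
tiny_spec <- function(...) {
  phantom_spec(amide_fractions = c(0.002, 0.005, 0.008),
               glu_concentrations = c(5, 15, 25),
               mt_fractions = c(0.08, 0.2),
               image_size = 24, vial_radius = 2, ...)
}

test_that("glutamate concentration / volume-fraction conversion is exact", {
  expect_equal(glu_conc_to_fraction(0), 0)
  expect_equal(glu_conc_to_fraction(20), 5.405405e-4, tolerance = 1e-6)
  x <- c(0, 3, 12.7, 25)
  expect_equal(fraction_to_glu_conc(glu_conc_to_fraction(x)), x,
               tolerance = 1e-12)
  expect_error(glu_conc_to_fraction(-1), ">= 0")
})

test_that("the default phantom enumerates 100 unique parameter combinations", {
  spec <- phantom_spec()
  expect_length(spec$amide_fractions, 5)
  expect_length(spec$glu_concentrations, 5)
  expect_length(spec$mt_fractions, 4)
  ph <- make_digital_phantom(spec, noise_sigma = 0)
  triples <- unique(do.call(rbind, lapply(1:4, function(ib) {
    cbind(f_amide = ph$truth$f_amide[, , ib][ph$vial_id > 0],
          glu = ph$truth$glu_mM[, , ib][ph$vial_id > 0],
          f_ss = ph$truth$f_ss[, , ib][ph$vial_id > 0])
  })))
  expect_equal(nrow(triples), 100)
})

test_that("truth maps contain exactly the specified values plus background", {
  ph <- make_digital_phantom(tiny_spec(), noise_sigma = 0)
  expect_setequal(unique(as.numeric(ph$truth$f_amide)),
                  c(0, 0.002, 0.005, 0.008))
  expect_setequal(unique(as.numeric(ph$truth$glu_mM)), c(0, 5, 15, 25))
  expect_setequal(unique(as.numeric(ph$truth$f_ss)), c(0, 0.08, 0.2))
})

test_that("pixels within a vial share a trajectory when noiseless", {
  ph <- make_digital_phantom(tiny_spec(), noise_sigma = 0)
  pix <- which(ph$vial_id == 5)[1:2]
  n <- nrow(ph$vial_id)
  m <- matrix(ph$traj$amide[, , , 1], n * n, dim(ph$traj$amide)[3])
  expect_identical(m[pix[1], ], m[pix[2], ])
  expect_true(all(m[ph$vial_id == 0, ] == 0))
})

test_that("a degenerate 1x1x1 spec yields a single combination", {
  spec <- phantom_spec(amide_fractions = 0.005, glu_concentrations = 10,
                       mt_fractions = 0.1, image_size = 16,
                       vial_radius = 2)
  ph <- make_digital_phantom(spec, noise_sigma = 0)
  vals <- ph$truth$f_amide[ph$vial_id > 0]
  expect_equal(unique(vals), 0.005)
  expect_equal(dim(ph$truth$f_ss)[3], 1)
})

test_that("vial geometry cannot overflow or overlap", {
  expect_error(phantom_spec(image_size = 16, vial_radius = 4),
               "overflow|overlap")
  expect_error(phantom_spec(image_size = 10, vial_radius = 3))
})

test_that("noise injection is unbiased, scaled by M0, and seeded", {
  m <- cbind(rep(2, 1e4), matrix(1, 1e4, 9))
  expect_identical(add_noise(m, 0), m)
  n1 <- add_noise(m, 0.01, seed = 3)
  n2 <- add_noise(m, 0.01, seed = 3)
  expect_identical(n1, n2)
  n3 <- add_noise(m, 0.01, seed = 4)
  expect_false(identical(n1, n3))
  # std of every entry is sigma * M0 = 0.02 (M0 = 2)
  expect_equal(sd(n1 - m), 0.02, tolerance = 0.02)
  expect_equal(mean(n1 - m), 0, tolerance = 1e-3)
  expect_error(add_noise(m, -0.1), ">= 0")
})

test_that("regeneration with different seeds changes only the noise", {
  spec <- tiny_spec()
  ph1 <- make_digital_phantom(spec, noise_sigma = 0.01, seed = 1)
  ph2 <- make_digital_phantom(spec, noise_sigma = 0.01, seed = 2)
  expect_identical(ph1$truth, ph2$truth)
  expect_identical(ph1$vial_id, ph2$vial_id)
  expect_false(identical(ph1$traj$mt, ph2$traj$mt))
  ph1b <- make_digital_phantom(spec, noise_sigma = 0.01, seed = 1)
  expect_identical(ph1$traj$mt, ph1b$traj$mt)
})

test_that("the saturated glutamate-protocol signal falls with concentration", {
  spec <- tiny_spec()
  ph <- make_digital_phantom(spec, noise_sigma = 0)
  n <- nrow(ph$vial_id)
  m <- matrix(ph$traj$glu[, , , 1], n * n, dim(ph$traj$glu)[3])
  # vials 1..3 share the lowest amide fraction and increase in glutamate
  sat_mean <- vapply(1:3, function(v)
    mean(m[ph$vial_id == v, -1]), numeric(1))
  expect_true(all(diff(sat_mean) < 0))
})
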