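test_that("ppm-to-angular-frequency conversion matches hand arithmetic", {
  expect_equal(ppm_to_angular_frequency(0, 7), 0)
  expect_equal(ppm_to_angular_frequency(1, 7), 2 * pi * 298.0348,
               tolerance = 1e-6)
  expect_equal(ppm_to_angular_frequency(-3.5, 7), -2 * pi * 1043.122,
               tolerance = 1e-6)
  expect_error(ppm_to_angular_frequency(1, -7), "positive")
})

test_that("free relaxation returns all longitudinal components to equilibrium", {
  tt <- tissue_model(1.8, 0.055,
                     list(pool("amide", 3.5, 1, 0.01, 200, 0.005),
                          pool("rnoe", -3.5, 1, 0.002, 20, 0.01)),
                     semisolid_pool(0.1, 40))
  st <- equilibrium_state(tt)
  st[grep("^z_", names(st))] <- st[grep("^z_", names(st))] * 0.1
  out <- evolve_state(st, tt, saturation_event(0, 0, 10 * 1.8))
  eq <- equilibrium_state(tt)
  zs <- grep("^z_", names(st))
  expect_true(all(abs(out[zs] - eq[zs]) <= 1e-3 * eq[zs]))
})

test_that("far-off-resonance saturation without exchange leaves water untouched", {
  tt <- tissue_model(1.8, 0.055,
                     list(pool("amide", 3.5, 1, 0.01, 200, 0)))
  eq <- equilibrium_state(tt)
  sat <- evolve_state(eq, tt, saturation_event(2, 100, 3))
  ref <- evolve_state(eq, tt, saturation_event(0, 100, 3))
  expect_gte(sat["z_water"], 0.999 * ref["z_water"])
})

test_that("two-pool steady state matches the closed-form oracle on randomized parameters", {
  set.seed(42)
  for (i in 1:20) {
    t1w <- runif(1, 1, 3); t2w <- runif(1, 0.04, 0.12)
    t1s <- runif(1, 0.5, 1.5); t2s <- runif(1, 0.005, 0.03)
    k <- runif(1, 50, 1000); f <- runif(1, 0.001, 0.01)
    b1 <- runif(1, 0.5, 4); off <- runif(1, 2, 5)
    tt <- two_pool_tissue(t1w, t2w, t1s, t2s, k, f)
    st <- evolve_state(equilibrium_state(tt), tt,
                       saturation_event(b1, off, 12 * t1w))
    z_oracle <- two_pool_steady_state_z(t1w, t2w, t1s, t2s, 3.5, k, f,
                                        b1, off)
    expect_lt(abs(st["z_water"] - z_oracle) / abs(z_oracle), 0.01)
  }
})

test_that("matrix-exponential and fine-step explicit integration agree", {
  set.seed(7)
  for (i in 1:20) {
    tt <- two_pool_tissue(runif(1, 1, 3), runif(1, 0.04, 0.12),
                          runif(1, 0.5, 1.5), runif(1, 0.005, 0.03),
                          runif(1, 20, 500), runif(1, 0.001, 0.01))
    ev <- saturation_event(runif(1, 0.3, 4), runif(1, -5, 5),
                           runif(1, 0.2, 1))
    eq <- equilibrium_state(tt)
    a <- evolve_state(eq, tt, ev, method = "expm")
    b <- evolve_state(eq, tt, ev, method = "rk4", step = 1e-5)
    expect_lt(abs(a["z_water"] - b["z_water"]), 1e-6)
  }
})

test_that("longitudinal magnetization relaxes monotonically without RF", {
  tt <- two_pool_tissue()
  st <- equilibrium_state(tt)
  st[grep("^z_", names(st))] <- 0
  eq <- equilibrium_state(tt)
  prev <- st
  for (dt in rep(0.2, 15)) {
    cur <- evolve_state(prev, tt, saturation_event(0, 0, dt))
    zs <- grep("^z_", names(cur))
    expect_true(all(cur[zs] >= prev[zs] - 1e-9))
    expect_true(all(cur[zs] <= eq[zs] + 1e-9))
    prev <- cur
  }
})

test_that("long saturation erases the initial state", {
  tt <- two_pool_tissue()
  ev <- saturation_event(2, 3.5, 10 * 1.5)
  a <- evolve_state(equilibrium_state(tt), tt, ev)
  st2 <- equilibrium_state(tt) * 0
  b <- evolve_state(st2, tt, ev)
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("a zero-volume-fraction pool leaves the trajectory unchanged", {
  sched <- default_schedule("mt")
  with_pool <- tissue_model(1.8, 0.055,
                            list(pool("amide", 3.5, 1, 0.01, 200, 0)))
  without <- tissue_model(1.8, 0.055)
  a <- simulate_trajectory(with_pool, sched)$values
  b <- simulate_trajectory(without, sched)$values
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("turning exchange off removes all but the direct-saturation contribution", {
  sched <- default_schedule("mt")  # offsets >= 6 ppm, far from the pool
  no_exchange <- tissue_model(1.8, 0.055,
                              list(pool("amide", 3.5, 1, 0.01, 0, 0.005)))
  without <- tissue_model(1.8, 0.055)
  exchanging <- tissue_model(1.8, 0.055,
                             list(pool("amide", 3.5, 1, 0.01, 200, 0.005)))
  a <- simulate_trajectory(no_exchange, sched)$values
  b <- simulate_trajectory(without, sched)$values
  c <- simulate_trajectory(exchanging, sched)$values
  expect_lt(max(abs(a - b)), 1e-3)          # only the far tail remains
  expect_gt(max(abs(c - b)), max(abs(a - b)))  # exchange adds real signal
})

test_that("tissue and pool validation rejects invalid parameters", {
  expect_error(pool("x", 3.5, t1 = -1, t2 = 0.01, 100, 0.01), "positive")
  expect_error(pool("x", 3.5, 1, 0.01, -5, 0.01), "non-negative")
  expect_error(pool("x", 3.5, 1, 0.01, 100, 1.2), "volume_fraction")
  expect_error(semisolid_pool(0.1, 40, t2 = 0.1), "microsecond")
  expect_error(tissue_model(0.04, 0.05), ">=")
  expect_error(tissue_model(1.8, 0.055,
                            list(pool("a", 3, 1, 0.01, 10, 0.6)),
                            semisolid_pool(0.5, 40)), "< 1")
})
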