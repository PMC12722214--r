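small_grid <- function() {
  parameter_grid(water_t1 = c(1.4, 1.8, 2.2),
                 f_ss = c(0.05, 0.1, 0.15, 0.2),
                 k_ssw = c(10, 30, 50, 70, 90))
}

test_that("dictionary rows enumerate the Cartesian product", {
  g <- small_grid()
  expect_equal(grid_size(g), 60)
  d <- generate_dictionary(g, default_schedule("mt"))
  expect_equal(nrow(d$params), 60)
  expect_equal(nrow(d$traj), 60)
  # declared order: first parameter varies fastest
  expect_equal(d$params[1:3, "water_t1"], c(1.4, 1.8, 2.2))
  expect_equal(d$params[1, "f_ss"], d$params[3, "f_ss"])
})

test_that("doubling one value list doubles the row count", {
  g1 <- small_grid()
  g2 <- parameter_grid(water_t1 = c(1.4, 1.8, 2.2),
                       f_ss = c(0.05, 0.1, 0.15, 0.2),
                       k_ssw = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100))
  expect_equal(grid_size(g2), 2 * grid_size(g1))
})

test_that("worker count does not change the result", {
  g <- parameter_grid(f_ss = c(0.05, 0.15), k_ssw = c(20, 50, 80))
  d1 <- generate_dictionary(g, default_schedule("mt"), workers = 1)
  d2 <- generate_dictionary(g, default_schedule("mt"), workers = 2)
  expect_identical(d1$traj, d2$traj)
})

test_that("duplicated grid values are deduplicated or rejected per config", {
  expect_message(g <- parameter_grid(f_ss = c(0.1, 0.1, 0.2),
                                     k_ssw = c(20, 50)),
                 "1 duplicated")
  expect_equal(grid_size(g), 4)
  expect_error(parameter_grid(f_ss = c(0.1, 0.1), k_ssw = c(20, 50),
                              duplicates = "error"), "duplicated")
})

test_that("grids reject unphysical values and oversized products", {
  expect_error(parameter_grid(f_ss = c(0.5, 1.2)), "\\[0, 1\\)")
  expect_error(parameter_grid(k_ssw = c(-5, 10)), ">= 0")
  expect_error(parameter_grid(bogus = 1), "unknown grid parameter")
  g <- small_grid()
  expect_error(generate_dictionary(g, default_schedule("mt"),
                                   max_rows = 10), "budget")
})

test_that("L2 normalization matches its definition", {
  expect_equal(l2_normalize(c(1, 3, 4)), c(0.6, 0.8))
  set.seed(1)
  m <- matrix(runif(50, 0.1, 1), 5, 10)
  nm <- l2_normalize(m)
  expect_equal(sqrt(rowSums(nm^2)), rep(1, 5), tolerance = 1e-9)
  expect_error(l2_normalize(c(1, 0, 0)), "zero-norm")
})

test_that("normalized dictionary rows are unit vectors and distinct", {
  g <- parameter_grid(f_ss = seq(0.04, 0.28, length.out = 10),
                      k_ssw = seq(10, 100, length.out = 10))
  d <- generate_dictionary(g, default_schedule("mt"))
  expect_gte(nrow(d$normalized), 100)
  expect_equal(sqrt(rowSums(d$normalized^2)), rep(1, nrow(d$normalized)),
               tolerance = 1e-9)
  dists <- dist(d$normalized)
  expect_gt(min(dists), 0)
})

test_that("dictionaries round-trip bit-exactly through the container", {
  g <- parameter_grid(f_ss = c(0.05, 0.15), k_ssw = c(20, 80))
  d <- generate_dictionary(g, default_schedule("mt"))
  f <- tempfile(fileext = ".rds")
  write_dictionary(d, f)
  d2 <- read_dictionary(f)
  expect_identical(d$params, d2$params)
  expect_identical(d$traj, d2$traj)
  expect_identical(d$schedule_hash, d2$schedule_hash)
  unlink(f)
})

test_that("the per-stage base tissue keeps only referenced mobile pools", {
  g_mt <- default_grid("mt")
  expect_length(.grid_base_tissue(g_mt)$solute_pools, 0)
  g_ag <- default_grid("amideglu")
  expect_setequal(names(.grid_base_tissue(g_ag)$solute_pools),
                  c("amide", "glu", "rnoe"))
  g_rn <- default_grid("rnoe")
  expect_setequal(names(.grid_base_tissue(g_rn)$solute_pools), "rnoe")
})
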