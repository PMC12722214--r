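# Independent reference implementations used to cross-check the package.

# Internal helpers exercised directly by the tests.
.schedule_matrix <- cestmrf:::.schedule_matrix
.tissue_cpp <- cestmrf:::.tissue_cpp
.grid_base_tissue <- cestmrf:::.grid_base_tissue
.lorentz <- cestmrf:::.lorentz
.sidecar_path <- cestmrf:::.sidecar_path

# Closed-form steady state of the two-pool (water + one solute)
# Bloch-McConnell system under continuous-wave irradiation: the fixed
# point of dM/dt = A M + c, assembled here independently of the C++
# propagation code and solved as a linear system.
two_pool_steady_state_z <- function(t1w, t2w, t1s, t2s, shift_ppm, k, f,
                                    b1_uT, offset_ppm, b0_field = 7) {
  gamma <- 42.5764e6
  w1 <- 2 * pi * gamma * b1_uT * 1e-6
  wpp <- 2 * pi * gamma * b0_field * 1e-6
  r1 <- c(1 / t1w, 1 / t1s); r2 <- c(1 / t2w, 1 / t2s)
  sh <- c(0, shift_ppm)
  kf <- k; kb <- f * k
  A <- matrix(0, 6, 6)
  ix <- c(1, 2); iy <- c(3, 4); iz <- c(5, 6)
  for (i in 1:2) {
    d <- wpp * (sh[i] - offset_ppm)
    A[ix[i], ix[i]] <- -r2[i]; A[ix[i], iy[i]] <- -d
    A[iy[i], ix[i]] <- d; A[iy[i], iy[i]] <- -r2[i]
    A[iy[i], iz[i]] <- w1
    A[iz[i], iy[i]] <- -w1; A[iz[i], iz[i]] <- -r1[i]
  }
  for (cc in list(ix, iy, iz)) {
    A[cc[2], cc[2]] <- A[cc[2], cc[2]] - kf
    A[cc[2], cc[1]] <- A[cc[2], cc[1]] + kb
    A[cc[1], cc[1]] <- A[cc[1], cc[1]] - kb
    A[cc[1], cc[2]] <- A[cc[1], cc[2]] + kf
  }
  cv <- rep(0, 6); cv[5] <- r1[1]; cv[6] <- r1[2] * f
  solve(A, -cv)[5]
}

# Hand-rolled two-way ANOVA mean-squares decomposition for the
# absolute-agreement single-measure ICC, written with explicit loops.
icc_a1_oracle <- function(x, y) {
  M <- cbind(x, y)
  n <- nrow(M); k <- ncol(M)
  grand <- sum(M) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(M[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(M[, j]) - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sst <- sst + (M[i, j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# One-way ANOVA F statistic from the explicit variance decomposition.
anova_f_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# A small water + amide test tissue used across physics tests.
two_pool_tissue <- function(t1w = 1.5, t2w = 0.05, t1s = 1, t2s = 0.01,
                            k = 150, f = 0.004, shift = 3.5) {
  tissue_model(t1w, t2w,
               list(pool("amide", shift, t1s, t2s, k, f)))
}
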