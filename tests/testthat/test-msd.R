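test_that("single-pair and ballistic MSDs are exact", {
  ## two-point trajectory, x = (0, 3 nm): MSD(1 step) = 9 nm^2
  tr <- new_trajectory(c(0, 9.6e-3), c(0, 3), c(0, 0), c(0, 0),
                       noise_floor_um2 = 0)
  m <- compute_msd(tr, axes = "x", lags = 1L, variance = FALSE)
  expect_equal(m$msd_um2, 9e-6)
  expect_equal(m$n_pairs, 1L)
  ## straight line: MSD(tau) = v^2 tau^2 at every lag
  v <- 150
  tr2 <- line_trajectory(v = v, n = 300)
  m2 <- compute_msd(tr2, axes = c("x", "y"), variance = FALSE)
  expect_equal(m2$msd_um2, (v * 1e-3 * m2$tau_s)^2, tolerance = 1e-10)
})

test_that("empty axis selection and bad lags are rejected", {
  tr <- line_trajectory()
  expect_error(compute_msd(tr, axes = character(0)))
  expect_error(compute_msd(tr, lags = 0L), "lags")
})

test_that("transverse Brownian MSD follows 4 D tau", {
  D <- 2e3
  msds <- sapply(1:20, function(i) {
    tr <- simulate_brownian(D, 5000, seed = 400 + i,
                            localization_sigma = 0)
    compute_msd(tr, lags = c(2L, 5L, 10L, 20L), variance = FALSE)$msd_um2
  })
  m <- rowMeans(msds) * 1e6
  tau <- c(2, 5, 10, 20) * 9.6e-3
  expect_equal(m / (4 * D * tau), rep(1, 4), tolerance = 0.03)
})

test_that("MSD is invariant under rigid translation and rotation", {
  tr <- simulate_brownian(2e3, 800, seed = 17)
  th <- 0.7
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                             y = sin(th) * x + cos(th) * y)
  r <- rot(tr$x_nm + 500, tr$y_nm - 300)
  tr2 <- new_trajectory(tr$t_s, r$x, r$y, tr$z_nm,
                        sampling_period = attr(tr, "sampling_period"))
  m1 <- compute_msd(tr, lags = c(1L, 5L, 25L), variance = FALSE)
  m2 <- compute_msd(tr2, lags = c(1L, 5L, 25L), variance = FALSE)
  expect_equal(m1$msd_um2, m2$msd_um2, tolerance = 1e-10)
})

test_that("concatenated independent trajectories give the pair-weighted MSD", {
  ## MSD of each piece at lag n, combined with weights K = N - n
  a <- simulate_brownian(1e3, 400, seed = 51, localization_sigma = 0)
  b <- simulate_brownian(1e3, 600, seed = 52, localization_sigma = 0)
  n <- 5L
  ma <- compute_msd(a, lags = n, variance = FALSE)
  mb <- compute_msd(b, lags = n, variance = FALSE)
  Ka <- 400 - n; Kb <- 600 - n
  pooled <- (ma$msd_um2 * Ka + mb$msd_um2 * Kb) / (Ka + Kb)
  ## equivalent direct computation over both pieces' pairs
  d2 <- c((a$x_nm[(1 + n):400] - a$x_nm[1:Ka])^2 +
            (a$y_nm[(1 + n):400] - a$y_nm[1:Ka])^2,
          (b$x_nm[(1 + n):600] - b$x_nm[1:Kb])^2 +
            (b$y_nm[(1 + n):600] - b$y_nm[1:Kb])^2) * 1e-6
  expect_equal(pooled, mean(d2), tolerance = 1e-12)
})

test_that("MSD variance estimator matches a brute-force ensemble", {
  ## 500 Brownian trajectories: mean analytic variance vs the observed
  ## ensemble variance of the time-averaged MSD, per axis
  D <- 2e3; N <- 1000; taus <- c(2L, 5L, 10L)
  msds <- matrix(0, 500, 3)
  kims <- matrix(0, 500, 3)
  for (i in 1:500) {
    tr <- simulate_brownian(D, N, seed = 6000 + i, localization_sigma = 0)
    m <- compute_msd(tr, axes = "x", lags = taus)
    msds[i, ] <- m$msd_um2
    kims[i, ] <- m$var_um4
  }
  ratio <- colMeans(kims) / apply(msds, 2, var)
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("variance estimator is additive over axes and zero for drift", {
  tr <- simulate_brownian(2e3, 1500, seed = 61)
  v3 <- msd_variance(tr, 5L, axes = c("x", "y", "z"))
  vx <- msd_variance(tr, 5L, axes = "x")
  vy <- msd_variance(tr, 5L, axes = "y")
  vz <- msd_variance(tr, 5L, axes = "z")
  expect_equal(as.numeric(v3), as.numeric(vx) + as.numeric(vy) +
                 as.numeric(vz), tolerance = 1e-12)
  ## deterministic drift: spread of squared differences is ~ 0
  lin <- line_trajectory(v = 100, n = 1500)
  vd <- msd_variance(lin, 5L, axes = "x")
  expect_lt(as.numeric(vd), 1e-20)
  ## out-of-regime lag is flagged, not silent
  vr <- msd_variance(tr, 400L, axes = "x")
  expect_equal(attr(vr, "flag"), "regime")
})

test_that("diffusion estimates invert the MSD correctly", {
  m <- viscous_msd()
  D_true <- attr(m, "D_nm2_s")
  est <- estimate_diffusion(m, method = "msd_at_lag", lag = 1)
  expect_equal(est$D_nm2_s, D_true, tolerance = 1e-9)
  est2 <- estimate_diffusion(m, method = "linear_fit", lag = 1)
  expect_equal(est2$D_nm2_s, D_true, tolerance = 1e-9)
})

test_that("recovered diffusion coefficient matches the generator", {
  D <- 2e3
  est <- sapply(1:10, function(i) {
    tr <- simulate_brownian(D, 1e4, seed = 700 + i)
    m <- compute_msd(tr, lags = log_lags_test(1, 110))
    estimate_diffusion(m, method = "msd_at_lag", lag = 1)$D_nm2_s
  })
  expect_equal(mean(est), D, tolerance = 0.1)
})

test_that("alpha fits recover Brownian, ballistic and subdiffusive motion", {
  tr <- simulate_brownian(2e3, 1e4, seed = 81, localization_sigma = 0)
  fa <- fit_alpha(compute_msd(tr, variance = FALSE))
  expect_lt(abs(fa$alpha - 1), 0.1)
  lin <- line_trajectory(v = 200, n = 2000)
  fl <- fit_alpha(compute_msd(lin, variance = FALSE))
  expect_equal(fl$alpha, 2, tolerance = 1e-6)
  al <- sapply(1:30, function(i) {
    f <- simulate_fbm(0.3, 1e4, 4096, seed = 900 + i)
    fit_alpha(compute_msd(f, variance = FALSE))$alpha
  })
  expect_lt(abs(mean(al) - 0.3), 0.05)
  ## spread is small and of the same order as the per-fit regression SE
  ## (OLS on correlated log-MSD points understates the true spread)
  f1 <- simulate_fbm(0.3, 1e4, 4096, seed = 901)
  se1 <- fit_alpha(compute_msd(f1, variance = FALSE))$alpha_se
  expect_lt(sd(al), 0.15)
  expect_gt(sd(al), se1 / 2)
})
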