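test_that("Mason method recovers the viscous limit exactly", {
  ## analytic MSD = 4 D tau with D from Stokes-Einstein: G' ~ 0,
  ## G''(f) = 2 pi f eta, delta = pi/2, Gamma(2) = 1
  eta <- 0.301; T_K <- 308.15; r <- 25
  m <- viscous_msd(eta = eta, T_K = T_K, radius_nm = r)
  mod <- mason_modulus(m, T_K = T_K, radius_nm = r)
  expect_equal(mod$alpha_local, rep(1, nrow(mod)), tolerance = 1e-6)
  expect_equal(mod$delta_rad, rep(pi / 2, nrow(mod)), tolerance = 1e-6)
  eta_hat <- mod$G_double_prime_Pa / (2 * pi * mod$f_hz)
  expect_equal(eta_hat, rep(eta, nrow(mod)), tolerance = 1e-6)
  expect_lt(max(abs(mod$G_prime_Pa)) / max(mod$G_double_prime_Pa), 1e-6)
  ## |G*|^2 = G'^2 + G''^2 by construction
  expect_equal(mod$G_abs_Pa^2,
               mod$G_prime_Pa^2 + mod$G_double_prime_Pa^2,
               tolerance = 1e-12)
})

test_that("GSER round trip on simulated viscous trajectories recovers eta", {
  eta <- 0.301; T_K <- 308.15; r <- 25
  kB <- 1.380649e-23
  D <- kB * T_K / (6 * pi * eta * r * 1e-9) * 1e18
  msds <- sapply(1:20, function(i) {
    tr <- simulate_brownian(D, 8000, seed = 1100 + i,
                            localization_sigma = 0)
    compute_msd(tr, lags = log_lags_test(2, 200, 40),
                variance = FALSE)$msd_um2
  })
  m0 <- compute_msd(simulate_brownian(D, 8000, seed = 1100,
                                      localization_sigma = 0),
                    lags = log_lags_test(2, 200, 40), variance = FALSE)
  m0$msd_um2 <- rowMeans(msds)
  mod <- mason_modulus(m0, T_K = T_K, radius_nm = r)
  mid <- mod$f_hz > quantile(mod$f_hz, 0.2) &
    mod$f_hz < quantile(mod$f_hz, 0.8)
  eta_hat <- median(mod$G_double_prime_Pa[mid] / (2 * pi * mod$f_hz[mid]))
  expect_equal(eta_hat, eta, tolerance = 0.05)
})

test_that("a flat MSD yields a purely elastic modulus", {
  taus <- 10^seq(-2, 1, length.out = 40)
  flat <- viscous_msd(taus = taus)
  flat$msd_um2 <- rep(2e-3, length(taus))
  mod <- mason_modulus(flat, T_K = 308.15, radius_nm = 25)
  expect_equal(mod$delta_rad, rep(0, nrow(mod)), tolerance = 1e-6)
  expect_lt(max(mod$G_double_prime_Pa) / max(mod$G_prime_Pa), 1e-6)
})

test_that("subdiffusive fBm gives loss angle pi alpha / 2", {
  msds <- sapply(1:20, function(i) {
    tr <- simulate_fbm(0.5, 2e3, 4096, seed = 1300 + i)
    compute_msd(tr, lags = log_lags_test(2, 300, 40),
                variance = FALSE)$msd_um2
  })
  m0 <- compute_msd(simulate_fbm(0.5, 2e3, 4096, seed = 1300),
                    lags = log_lags_test(2, 300, 40), variance = FALSE)
  m0$msd_um2 <- rowMeans(msds)
  mod <- mason_modulus(m0, T_K = 308.15, radius_nm = 25)
  mid <- mod$f_hz > quantile(mod$f_hz, 0.25) &
    mod$f_hz < quantile(mod$f_hz, 0.75)
  expect_equal(median(mod$delta_rad[mid]), pi / 4, tolerance = 0.08)
})

test_that("hotter (larger-amplitude) dataset gives lower |G*| at fixed f", {
  mk <- function(scale, seed) {
    msds <- sapply(1:10, function(i) {
      tr <- simulate_fbm(0.6, scale, 4096, seed = seed + i)
      compute_msd(tr, lags = log_lags_test(2, 300, 30),
                  variance = FALSE)$msd_um2
    })
    m0 <- compute_msd(simulate_fbm(0.6, scale, 4096, seed = seed),
                      lags = log_lags_test(2, 300, 30), variance = FALSE)
    m0$msd_um2 <- rowMeans(msds)
    mason_modulus(m0, T_K = 308.15, radius_nm = 25)
  }
  cold <- mk(2e3, 1400)
  hot <- mk(2e3 * 1.6, 1500)
  i <- which.min(abs(cold$f_hz - 2.7))
  j <- which.min(abs(hot$f_hz - 2.7))
  expect_lt(hot$G_abs_Pa[j], cold$G_abs_Pa[i])
})

test_that("Welch PSD localizes a sinusoid and preserves variance", {
  dt <- 9.6e-3; n <- 12000
  t_s <- (seq_len(n) - 1) * dt
  x <- 50 * sin(2 * pi * 40 * t_s)
  tr <- new_trajectory(t_s, x, rep(0, n), rep(0, n), sampling_period = dt)
  p <- welch_psd(tr, window = 9.6)
  expect_equal(p$f_hz[which.max(p$psd_x_um2_hz)], 40, tolerance = 0.02)
  ## Parseval: integrated density ~ signal variance (Hann-windowed
  ## segments resolve the line fully)
  tot <- sum(p$psd_x_um2_hz) * diff(p$f_hz)[1]
  expect_equal(tot, var(x * 1e-3), tolerance = 0.05)
  expect_error(welch_psd(tr, window = 1e4), "longer")
})

test_that("Brownian PSD falls as 1/f^2", {
  tr <- simulate_brownian(2e3, 3e4, seed = 1600, localization_sigma = 0)
  p <- welch_psd(tr, window = 28.8)
  band <- p$f_hz > 0.5 & p$f_hz < 20
  sl <- coef(lm(log(psd_total_um2_hz) ~ log(f_hz),
                data = p[band, ]))[2]
  expect_lt(abs(sl + 2), 0.1)
  ## one-sided normalization: total transverse PSD ~ 2 * D / (pi^2 f^2)
  Dhat <- mean(p$psd_total_um2_hz[band] * pi^2 * p$f_hz[band]^2) / 2 * 1e6
  expect_equal(Dhat, 2e3, tolerance = 0.15)
})

test_that("equilibrium force decomposition finds no active forces", {
  eta <- 0.301; T_K <- 308.15; r <- 25
  kB <- 1.380649e-23
  D <- kB * T_K / (6 * pi * eta * r * 1e-9) * 1e18
  tr <- simulate_brownian(D, 3e4, seed = 1700, localization_sigma = 0)
  p <- welch_psd(tr, window = 28.8)
  mod <- mason_modulus(viscous_msd(eta = eta, T_K = T_K, radius_nm = r),
                       T_K = T_K, radius_nm = r)
  dec <- decompose_forces(p, mod, T_K = T_K, radius_nm = r)
  ## external force PSD small relative to the total force scale
  rel <- dec$F_ext2_N2_hz / (dec$K_abs_N_m^2 * dec$psd_um2_hz * 1e-12)
  expect_lt(median(rel), 0.3)
  ## thermal bound tracks the measured PSD in equilibrium
  expect_equal(median(dec$thermal_um2_hz / dec$psd_um2_hz), 1,
               tolerance = 0.25)
})

test_that("injected kicks raise the inferred active force monotonically", {
  eta <- 0.301; T_K <- 308.15; r <- 25
  kB <- 1.380649e-23
  D <- kB * T_K / (6 * pi * eta * r * 1e-9) * 1e18
  base <- simulate_brownian(D, 2e4, seed = 1800, localization_sigma = 0)
  mod <- mason_modulus(viscous_msd(eta = eta, T_K = T_K, radius_nm = r),
                       T_K = T_K, radius_nm = r)
  med_force <- sapply(c(0, 30, 90), function(amp) {
    set.seed(1801)
    kick <- amp * cumsum(rnorm(nrow(base)))
    tr <- new_trajectory(base$t_s, base$x_nm + kick, base$y_nm, base$z_nm,
                         sampling_period = 9.6e-3)
    p <- welch_psd(tr, window = 28.8)
    dec <- decompose_forces(p, mod, T_K = T_K, radius_nm = r)
    median(dec$F_ext2_N2_hz)
  })
  expect_true(all(diff(med_force) > 0))
})

test_that("doubling the spring constant quadruples the implied force PSD", {
  ## algebra of the Hooke's-law decomposition at fixed position PSD
  K <- 2e-6; Sx <- 1e-15
  expect_equal(((2 * K)^2 * Sx) / (K^2 * Sx), 4)
})

test_that("hydrodynamic radius recovery from D(T)", {
  med <- medium_model(particle_radius = 25)
  temps <- seq(24, 41.5, by = 3.5)
  kB <- 1.380649e-23
  D_true <- sapply(temps, function(T_C) {
    kB * (T_C + 273.15) /
      (6 * pi * glycerol_viscosity(T_C, med, warn = FALSE) * 25e-9) * 1e18
  })
  ## noiseless: exact recovery
  fit0 <- stokes_einstein_radius(
    tibble::tibble(temperature_C = temps, D_nm2_s = D_true), med)
  expect_equal(fit0$radius_nm, 25, tolerance = 1e-9)
  ## single point: direct inversion
  fit1 <- stokes_einstein_radius(
    tibble::tibble(temperature_C = temps[4], D_nm2_s = D_true[4]), med)
  expect_equal(fit1$radius_nm, 25, tolerance = 1e-9)
  ## 5% noise on D over 6 temperatures: within +/- 1 nm on average
  set.seed(2025)
  rs <- replicate(100, {
    D_obs <- D_true * (1 + rnorm(6, sd = 0.05))
    stokes_einstein_radius(
      tibble::tibble(temperature_C = temps, D_nm2_s = D_obs), med)$radius_nm
  })
  expect_lt(abs(mean(rs) - 25), 1)
  expect_lt(sd(rs), 1.5)
  ## tidy/glance expose the estimate
  td <- tidy(fit0)
  expect_equal(td$estimate[td$term == "radius_nm"], 25, tolerance = 1e-9)
})
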