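test_that("template equals the dip profile for noiseless data", {
  model <- spectrum_model()
  o <- generate_odmr_series(0, model = model, duration = 1, noise = "none")
  tpl <- build_template(o)
  prof <- odmr_profile(tpl$frequency_grid, model)
  expect_equal(tpl$values, prof / mean(prof), tolerance = 1e-12)
  ## piecewise linearity: value at a grid midpoint is the mean of the
  ## neighbouring grid values
  f1 <- tpl$frequency_grid[10]; f2 <- tpl$frequency_grid[11]
  expect_equal(template_eval(tpl, (f1 + f2) / 2),
               (tpl$values[10] + tpl$values[11]) / 2, tolerance = 1e-12)
})

test_that("template from Poisson data converges to the analytic profile", {
  model <- spectrum_model()
  o <- generate_odmr_series(0, model = model, duration = 30, seed = 3)
  tpl <- build_template(o)
  prof <- odmr_profile(tpl$frequency_grid, model)
  prof <- prof / mean(prof)
  ## per-point SE of the normalized mean of 150 windows of Poisson counts
  lam <- 800 * odmr_profile(tpl$frequency_grid, model)
  se <- sqrt(lam / 150) / mean(lam)
  expect_true(all(abs(tpl$values - prof) < 4 * se))
})

test_that("all-zero counts are rejected", {
  o <- generate_odmr_series(0, duration = 1, noise = "none")
  o$counts <- 0
  expect_error(build_template(o), "All-zero")
})

test_that("shift fitting is self-consistent and translation-equivariant", {
  model <- spectrum_model()
  o <- generate_odmr_series(0, model = model, duration = 1, noise = "none")
  tpl <- build_template(o)
  fgrid <- tpl$frequency_grid
  lam <- 160 * model$baseline_rate * 1e-5 * odmr_profile(fgrid, model)
  ## identical bin and template: zero shift
  r0 <- fit_frequency_shift(lam, tpl)
  expect_lt(abs(r0$df_khz), 1)
  ## bin generated from the profile shifted by -120 kHz
  lam_sh <- 160 * model$baseline_rate * 1e-5 *
    odmr_profile(fgrid, model, model$center_frequency - 0.120)
  r1 <- fit_frequency_shift(lam_sh, tpl)
  expect_equal(r1$df_khz, -120, tolerance = 1)
  ## equivariance: a further -180 kHz moves the estimate by -180 kHz
  lam_sh2 <- 160 * model$baseline_rate * 1e-5 *
    odmr_profile(fgrid, model, model$center_frequency - 0.300)
  r2 <- fit_frequency_shift(lam_sh2, tpl)
  expect_equal(r2$df_khz - r1$df_khz, -180, tolerance = 2)
  ## amplitude and offset nuisance parameters are absorbed
  r3 <- fit_frequency_shift(3.7 * lam_sh + 40, tpl)
  expect_equal(r3$df_khz, r1$df_khz, tolerance = 1)
})

test_that("Poisson-noise shift estimates are unbiased with consistent SE", {
  model <- spectrum_model()
  tpl <- build_template(generate_odmr_series(0, model = model,
                                             duration = 1, noise = "none"))
  fgrid <- tpl$frequency_grid
  lam <- 160 * model$baseline_rate * 1e-5 *
    odmr_profile(fgrid, model, model$center_frequency - 0.100)
  set.seed(77)
  fits <- t(replicate(100, {
    y <- rpois(length(lam), lam)
    as.numeric(fit_frequency_shift(y, tpl)[1, c("df_khz", "se_khz")])
  }))
  expect_equal(mean(fits[, 1]), -100, tolerance = 3 * sd(fits[, 1]) / 10)
  ## reported SE within ~40% of the Monte-Carlo scatter
  expect_gt(mean(fits[, 2]) / sd(fits[, 1]), 0.6)
  expect_lt(mean(fits[, 2]) / sd(fits[, 1]), 1.4)
})

test_that("shift averaging produces block means with standard errors", {
  o <- generate_odmr_series(0, duration = 40, seed = 4)
  s <- fit_shift_series(o)
  ## constant (duplicated) shifts: SE = 0
  s0 <- s
  s0$df_khz <- rep(5, nrow(s0))
  a0 <- average_shifts(s0, n_f = 10)
  expect_equal(a0$df_khz, rep(5, nrow(a0)))
  expect_equal(a0$se_khz, rep(0, nrow(a0)))
  ## i.i.d. Gaussian shifts with n_f = 25: SE ~ sigma / 5
  set.seed(8)
  s1 <- fit_shift_series(generate_odmr_series(0, duration = 500, seed = 9))
  sig <- sd(s1$df_khz)
  a1 <- average_shifts(s1, n_f = 25)
  expect_equal(mean(a1$se_khz), sig / 5, tolerance = 0.2)
  ## n_f = 1 rejected; trailing partial block dropped with a warning
  expect_error(average_shifts(s1, n_f = 1), "allowed range")
  expect_warning(average_shifts(s1[1:52, ], n_f = 25), "partial")
})

test_that("temperature conversion follows dT = df / kappa", {
  cal <- thermometry_calibration(kappa = -60)
  expect_equal(shift_to_temperature(-240, cal), 4)
  expect_equal(shift_to_temperature(0, cal), 0)
  expect_equal(shift_to_temperature(-60, cal), 1)
  expect_error(thermometry_calibration(kappa = 0), "non-zero")
})

test_that("thermal shift coefficient is recovered from calibration data", {
  ## programmed temperature steps; fitted shifts regressed on dT
  model <- spectrum_model()
  kappa_in <- -60
  dTs <- c(0, 4, 8, 12)
  shifts <- sapply(seq_along(dTs), function(i) {
    o <- generate_odmr_series(dTs[i], model = model, kappa = kappa_in,
                              duration = 30, seed = 40 + i)
    tpl <- build_template(generate_odmr_series(0, model = model,
                                               duration = 30, seed = 30))
    mean(fit_shift_series(o, template = tpl)$df_khz)
  })
  fit <- lm(shifts ~ dTs)
  kappa_hat <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(kappa_hat - kappa_in), max(3 * se, 1))
})

test_that("square-wave temperature profile is recovered within error", {
  profile <- function(t) 4 * (floor(t / 60) %% 2)
  o <- generate_odmr_series(profile, duration = 240, seed = 12)
  s <- fit_shift_series(o)
  a <- average_shifts(s, n_f = 25)
  temp <- shift_to_temperature(a)
  truth <- profile(temp$t_s + 5)
  ## the template centres on the record mean, so compare mean-centred
  mae <- mean(abs((temp$dT_C - mean(temp$dT_C)) - (truth - mean(truth))))
  expect_lt(mae, 2 * mean(temp$se_C))
})
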