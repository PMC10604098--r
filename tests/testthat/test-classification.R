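test_that("directionality ratio geometry is exact", {
  dt <- 9.6e-3
  mk <- function(x, y) {
    n <- length(x)
    new_trajectory((0:(n - 1)) * dt, x, y, rep(0, n), sampling_period = dt)
  }
  ## collinear equal steps
  expect_equal(directionality_ratio(mk(c(0, 1, 2, 3), rep(0, 4))), 1)
  ## closed square path
  sq <- mk(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(directionality_ratio(sq), 0)
  ## two equal perpendicular steps
  expect_equal(directionality_ratio(mk(c(0, 1, 1), c(0, 0, 1))),
               sqrt(2) / 2)
  ## stationary window: gamma 0 with a warning
  expect_warning(g <- directionality_ratio(mk(rep(0, 5), rep(0, 5))),
                 "Stationary")
  expect_equal(g, 0)
  expect_error(directionality_ratio(mk(c(0, 1), c(0, 0))), "at least 2")
})

test_that("gamma is invariant under rigid rotation and translation", {
  tr <- simulate_brownian(2e3, 200, seed = 2100)
  th <- 1.1
  x2 <- cos(th) * tr$x_nm - sin(th) * tr$y_nm + 900
  y2 <- sin(th) * tr$x_nm + cos(th) * tr$y_nm - 250
  tr2 <- new_trajectory(tr$t_s, x2, y2, tr$z_nm,
                        sampling_period = 9.6e-3)
  expect_equal(directionality_ratio(tr), directionality_ratio(tr2),
               tolerance = 1e-12)
})

test_that("null threshold is reproducible and decreases with window length", {
  g1 <- gamma_null_threshold(2e3, window = 50, seed = 22)
  g2 <- gamma_null_threshold(2e3, window = 50, seed = 22)
  expect_identical(g1, g2)
  g_long <- gamma_null_threshold(2e3, window = 200, seed = 22)
  expect_gt(g1, g_long)
  expect_true(g1 > 0 && g1 < 1)
  expect_error(gamma_null_threshold(2e3, n_sim = 50), "at least 100")
  ## a ballistic window always exceeds the threshold
  lin <- line_trajectory(v = 100, n = 51)
  expect_gt(directionality_ratio(lin), g1)
})

test_that("segmentation false-positive rate matches the null quantile", {
  q <- 0.99
  gstar <- gamma_null_threshold(2e3, window = 50, quantile = q,
                                n_sim = 1e4, seed = 23)
  ## fraction of sliding windows flagged on fresh Brownian data
  n_flag <- 0; n_tot <- 0
  for (i in 1:5) {
    tr <- simulate_brownian(2e3, 4000, seed = 2300 + i,
                            localization_sigma = 0)
    xy <- as.matrix(tr[, c("x_nm", "y_nm")])
    steps <- sqrt(rowSums(diff(xy)^2))
    cl <- cumsum(c(0, steps))
    i0 <- seq_len(nrow(xy) - 50)
    l <- cl[i0 + 50] - cl[i0]
    d <- sqrt((xy[i0 + 50, 1] - xy[i0, 1])^2 +
                (xy[i0 + 50, 2] - xy[i0, 2])^2)
    n_flag <- n_flag + sum(d / l > gstar)
    n_tot <- n_tot + length(i0)
  }
  p_hat <- n_flag / n_tot
  ## overlapping windows correlate, so allow a generous binomial-style
  ## band around 1 - q
  expect_lt(p_hat, 0.05)
  ## and no long directed segments on pure Brownian data
  tr <- simulate_brownian(2e3, 4000, seed = 2400, localization_sigma = 0)
  seg <- segment_trajectory(tr, window = 50, gamma_star = gstar)
  expect_true(all(seg$label == "nondirected") ||
                sum(seg$end_s[seg$label == "directed"] -
                      seg$start_s[seg$label == "directed"]) < 0.1 *
                max(tr$t_s))
})

test_that("an inserted drift interval is recovered as a directed segment", {
  dur <- 120; dt <- 9.6e-3
  base <- simulate_brownian(2e3, dur / dt, seed = 25,
                            localization_sigma = 0)
  tr <- insert_directed_interval(base, v = 400, from_s = 50, to_s = 55)
  gstar <- gamma_null_threshold(2e3, window = 50, seed = 26)
  seg <- segment_trajectory(tr, window = 50, gamma_star = gstar)
  dir <- seg[seg$label == "directed", ]
  expect_gt(nrow(dir), 0)
  overlap <- sum(pmax(0, pmin(dir$end_s, 55) - pmax(dir$start_s, 50)))
  expect_gt(overlap / 5, 0.8)
  ## segments are disjoint and ordered
  expect_true(all(diff(seg$start_index) > 0))
  expect_true(all(seg$start_index[-1] >= head(seg$end_index, -1)))
})

test_that("short or stationary trajectories give one nondirected segment", {
  tr <- simulate_brownian(1e3, 30, seed = 27)
  seg <- segment_trajectory(tr, window = 50, gamma_star = 0.5)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$label, "nondirected")
})

test_that("exponent summaries fit and classify mixtures", {
  s0 <- summarize_alphas(rep(1, 5))
  expect_equal(s0$fitted_mean, 1)
  expect_equal(s0$fitted_sd, 0)
  expect_equal(sum(s0$class_fractions), 1)
  ## directed-preset exponents: superdiffusive mean
  set.seed(28)
  a_dir <- rnorm(60, 1.65, 0.05)
  s_dir <- summarize_alphas(a_dir)
  expect_gt(s_dir$fitted_mean, 1.5)
  expect_gt(s_dir$class_fractions["super"], 0.95)
  ## two-preset mixture split by labels recovers both centres
  a_non <- rnorm(60, 0.97, 0.05)
  s_non <- summarize_alphas(a_non)
  expect_lt(abs(s_non$fitted_mean - 0.97), 0.03)
  expect_lt(abs(s_dir$fitted_mean - 1.65), 0.03)
  g <- glance(s_dir)
  expect_equal(g$n, 60L)
  expect_error(summarize_alphas(c(1, 2)), "at least 3")
})

test_that("removing the drift moves fitted exponents back to diffusive", {
  fits <- function(v) {
    sapply(1:20, function(i) {
      tr <- simulate_directed(v, 2e3, c(1, 1, 0), 4000, seed = 2900 + i,
                              localization_sigma = 0)
      fit_alpha(compute_msd(tr, variance = FALSE))$alpha
    })
  }
  with_drift <- mean(fits(300))
  without <- mean(fits(0))
  expect_gt(with_drift, 1.5)
  expect_lt(abs(without - 1), 0.05)
})
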