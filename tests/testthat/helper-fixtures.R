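## Shared fixture builders. All synthetic data are generated in code
## under fixed seeds; no files are read.

## Log-spaced integer lags (duplicated from the package internals so
## tests run against the installed namespace).
log_lags_test <- function(lo, hi, n = 60) {
  unique(round(exp(seq(log(lo), log(hi), length.out = n))))
}

## The glycerol preset's programmed temperature profile (degC offsets).
preset_profile_for_tests <- function(cfg) {
  function(t) 3.5 * (floor(t / 300) %% 2)
}

## A deterministic straight-line trajectory x = v * t.
line_trajectory <- function(v = 100, n = 200, dt = 9.6e-3) {
  t_s <- (seq_len(n) - 1) * dt
  new_trajectory(t_s, v * t_s, rep(0, n), rep(0, n),
                 sampling_period = dt, noise_floor_um2 = 0)
}

## An analytic viscous-medium MSD curve (transverse, 4 D tau) wrapped
## as an nd_msd, for closed-form GSER checks.
viscous_msd <- function(eta = 0.301, T_K = 308.15, radius_nm = 25,
                        taus = 10^seq(-2, 1, length.out = 60)) {
  kB <- 1.380649e-23
  D_nm2_s <- kB * T_K / (6 * pi * eta * radius_nm * 1e-9) * 1e18
  msd_um2 <- 4 * D_nm2_s * taus * 1e-6
  out <- tibble::tibble(lag = seq_along(taus), tau_s = taus,
                        msd_um2 = msd_um2, var_um4 = NA_real_,
                        error_um2 = NA_real_,
                        n_pairs = rep(1e6L, length(taus)),
                        flag = "ok")
  structure(out, class = c("nd_msd", class(out)),
            axes = c("x", "y"), sampling_period = diff(taus)[1],
            n_samples = 1e6L, noise_floor_um2 = 0,
            D_nm2_s = D_nm2_s, eta = eta)
}
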