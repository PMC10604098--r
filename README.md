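# diamondsense

Dual-modality nanodiamond sensing analysis in R: **nanothermometry** from
optically detected magnetic resonance (ODMR) of nitrogen-vacancy (NV)
centres, and **nanorheometry** from single-particle tracking of the same
nanodiamond — temperature and mechanics read out simultaneously and
independently from one probe.

The package is for researchers analysing (or planning) NV-nanodiamond
tracking experiments in fluids, gels and live cells, and for anyone who
needs well-tested reference implementations of the underlying estimators.
No public datasets exist for this class of experiment, so the package also
ships first-class synthetic generators that emulate the instrument — the
double-plane orbital tracker, the duty-cycled ODMR photon stream, the
resistive reference thermometer — and the particle-motion models (Brownian,
fractional Brownian, directed).

## What it computes

**Thermometry.** ODMR spectra are fitted by the interpolation method: a
piece-wise-linear template built from the whole record, shifted to fit each
400 ms bin with free amplitude/offset, giving frequency shifts δf that
convert to temperature through the NV thermal shift coefficient
κ = −60.0 kHz/°C (ΔT = δf/κ). Precision versus accumulation time is
characterized by the overlapping Allan deviation; the extracted sensitivity
(K/√Hz, from the white-noise region) is benchmarked against the shot-noise
Cramér–Rao bound computed from the Poisson Fisher information of the same
spectrum model and photon budget.

**Rheometry.** The time-averaged MSD, MSD(τ) = K⁻¹ Σᵢ |**r**(i+τ) −
**r**(i)|², carries an analytic single-trajectory variance estimate that
accounts for the correlation of overlapping pairs, plus a 10⁻⁴ μm² noise
floor rule. From the MSD: diffusion coefficients (D = MSD/4τ transverse),
hydrodynamic radii via Stokes–Einstein across temperatures, and
frequency-dependent viscoelastic moduli via the Mason generalized
Stokes–Einstein relation, |G*| = 2k_BT / (3πr · MSD(1/ω) · Γ(1+α)) with
loss angle δ = πα/2. Welch position PSDs combine with the complex spring
constant K(ω) = 6πr·G*(ω) to split thermal from active (e.g. motor-driven)
force contributions by Hooke's law.

**Motion classification.** Trajectory segments with statistically
significant directional persistence are detected with the directionality
ratio γ = d/l against a matched Brownian Monte-Carlo null; per-segment
anomalous exponents α (MSD ∝ τ^α) are fitted and summarized into
sub/diffusive/superdiffusive populations.

## Worked example

Temperature and rheology from synthetic data emulating a glycerol
experiment:

```r
library(diamondsense)

## --- rheometry: D at 1 s lag, then the hydrodynamic radius from D(T) ---
traj <- simulate_brownian(D = 2e3, n_steps = 2e4, seed = 11)
msd  <- compute_msd(traj)                      # transverse, with variance
estimate_diffusion(msd, method = "msd_at_lag", lag = 1)
#> # A tibble: 1 x 6
#>   D_nm2_s se_nm2_s method     lag_used_s n_axes flag
#>     <dbl>    <dbl> <chr>           <dbl>  <int> <chr>
#> 1   1973.     126. msd_at_lag      0.989      2 ok

temps  <- seq(24, 41.5, by = 3.5)              # 6 temperature setpoints
D_of_T <- sapply(seq_along(temps), function(i) {
  tr <- simulate_brownian(stokes_einstein_D(temps[i]), 1e4, seed = 20 + i)
  estimate_diffusion(compute_msd(tr), "msd_at_lag", lag = 1)$D_nm2_s
})
stokes_einstein_radius(tibble::tibble(temperature_C = temps, D_nm2_s = D_of_T))
#> <nd_stokes_fit> hydrodynamic radius 24.86 nm (se 0.59) from 6 temperature points
```

The generator used a 25 nm particle; the fit recovers 24.9 ± 0.6 nm. The
estimated D ≈ 1973 nm²/s agrees with the programmed 2 × 10³ nm²/s within
its standard error.

```r
## --- thermometry: a 4 degC square wave, 1-min period, 4-min record ------
odmr   <- generate_odmr_series(function(t) 4 * (floor(t / 60) %% 2),
                               duration = 240, seed = 12)
shifts <- fit_shift_series(odmr)               # template from the record
temp   <- shift_to_temperature(average_shifts(shifts, n_f = 25))
head(temp, 3)                                  # 10-s blocks, degC vs record mean
#>     t_s  dT_C  se_C
#> 1     0 -3.71 0.734
#> 2    10 -1.18 0.739
#> 3    20 -1.91 0.743

sens <- benchmark_sensitivity(allan_sensitivity(shift_to_temperature(shifts)),
                              cramer_rao_sensitivity(spectrum_model()))
sens
#> <nd_sensitivity> white-noise region found; sensitivity 2.212 K/sqrt(Hz) (CRB 2.151, excess 2.8%)
```

Because the template is built from the record itself, temperatures are read
relative to the record mean (here 2 °C): cold bins sit near −2, hot bins
near +2, and the hot−cold contrast recovers ≈ 3.6 of the programmed 4 °C on
this short record with ≈ 0.7 °C error bars per 10 s block. The
Allan-deviation sensitivity of this shot-noise-limited run sits 2.8 % above
the Cramér–Rao bound.

End-to-end runs — both modalities from one programmed temperature profile
on a shared clock — go through `run_pipeline(run_config("glycerol", ...))`;
see the vignette (`vignettes/dual-modality-nanosensing.Rmd`) for the models,
parameter defaults and design decisions.

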