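---
title: "Dual-modality nanodiamond sensing: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality nanodiamond sensing: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(diamondsense)
library(ggplot2)
```

Nitrogen-vacancy (NV) centres in nanodiamonds make unusual probes: the same
particle reports the local temperature (through the thermal shift of its
optically detected magnetic resonance, ODMR) and the local mechanics (through
its own thermal motion, read out by single-particle tracking). `diamondsense`
implements the full analysis chain for such a dual-modality sensor — and,
because no public datasets exist for this kind of experiment, it also ships
first-class synthetic generators that emulate the instrument: the orbital
tracker, the ODMR photon stream, the resistive reference thermometer, and a
family of particle-motion models. All package results in this vignette and in
the test suite are computed from these generators under fixed seeds.

This vignette explains the models, the estimators, the tunable parameters and
the design decisions — in the spirit of an instrument paper's methods section,
but for the software.

## The synthetic instrument

### Particle motion

Three generators cover the motion regimes seen in practice:

* `simulate_brownian(D, ...)` — free diffusion with per-axis increment
  variance $2D\,\Delta t$. The default sampling period is 9.6 ms, the update
  period of the orbital tracker.
* `simulate_fbm(alpha, scale, ...)` — fractional Brownian motion with Hurst
  index $\alpha/2$, giving an ensemble MSD $\propto \tau^\alpha$ per axis.
  Fractional Gaussian increments are generated by exact circulant embedding
  (Davies–Harte); no installed package provides them. Subdiffusive
  ($\alpha < 1$) settings emulate crowded, viscoelastic cytoplasm;
  superdiffusive settings are available for completeness, though directed
  transport is better modelled explicitly.
* `simulate_directed(v, D, ...)` — drift $v t$ plus diffusion, the standard
  model for motor-driven transport. Its transverse MSD is exactly
  $4D\tau + (v_\perp\tau)^2$.

All generators add isotropic Gaussian localization noise. Its default
standard deviation, 5 nm per axis, is chosen so that the static transverse
MSD plateau $4\sigma^2$ equals the $10^{-4}\,\mu\text{m}^2$ system noise
floor of the tracking hardware being emulated. Every stochastic function
takes an explicit `seed` and is bit-reproducible.

What the generators deliberately do *not* emulate: spatial heterogeneity of
the medium, photobleaching or blinking (nanodiamond NV photoluminescence is
stable), tracker nonlinearities at large displacement, and microscope drift.
A passing test on synthetic data therefore demonstrates estimator
correctness under the stated motion model, not robustness to every artefact
of real recordings.

### The ODMR photon stream

`generate_odmr_series()` reproduces the continuous-wave ODMR acquisition
cycle: a 200-point microwave sweep completed in 2 ms, 80 sweeps accumulated
in a 160 ms window, and a 40 ms off period per 200 ms duty cycle (the off
time is when the sample heater may act; no photons are collected then). At
the nominal 1 Mcps photoluminescence rate, each 10 µs frequency gate
delivers about 5 counts per APD — two detectors are summed. Counts are
Poisson; a `noise = "none"` switch gives the infinite-photon-budget limit
used by exactness tests.

The line shape is a unit-baseline profile with two Lorentzian dips split
symmetrically about the centre (default contrast 0.2, FWHM 6 MHz, splitting
8 MHz), configurable to a single dip. An ensemble-NV nanodiamond spectrum is
strain-split in practice; the exact parameterization matters little because
the thermometry pipeline is template-based, but the symmetric shape has one
important consequence: the amplitude/offset nuisance parameters of the shift
fit are asymptotically orthogonal to the centre frequency, so allowing for
photoluminescence drift costs essentially no sensitivity.

The dip centre tracks temperature linearly with coefficient
$\kappa = -60.0$ kHz/°C (the empirical NV thermal shift near room
temperature), exposed in `thermometry_calibration()`.

Counts are stored aggregated per window — the sum over the 80 sweeps per
frequency point — matching the instrument's own intermediate storage. With a
constant temperature within each 160 ms window (true for all profiles used,
which step on multi-second scales), the per-window sum of Poisson draws is
exactly Poisson, so nothing is lost. A 30-minute record is 1.8 M values.

### The orbital tracker

`simulate_tracker()` closes the feedback loop of double-plane orbital
tracking: the excitation beam orbits the last inferred particle position
(radius 50 nm) while two detection arms observe planes offset by ±50 nm
axially. Counts along the orbit are Poisson draws from a 3D Gaussian PSF
(transverse $1/e^2$ radius 250 nm; axial radius twice that, the usual
confocal elongation). The transverse correction is the first Fourier
harmonic of the counts around the orbit, linearized as
$\hat\delta_x = a_1 w_0^2 / 4R$; the axial correction is the log-ratio of
plane counts, $\hat\delta_z = w_z^2 \ln(N_t/N_b)/4s$. Both estimators are
unbiased at the fixed point, which the noiseless-limit test verifies
exactly. With shot noise at 1 Mcps the closed-loop RMS error settles at a
few nanometres per 9.6 ms update — the same scale as the hardware the
simulator emulates — and grows with the diffusion coefficient of the
tracked particle, as the dynamic-accuracy test checks. A particle whose
tracking error exceeds three PSF radii is flagged as lost rather than
silently continued.

The feedback law in the real instrument ("linear search and quadratic
minimization" in its firmware) is not public; what the simulator fixes is
the *contract* — unbiased fixed point, shot-noise-limited error — not the
exact algorithm.

## Thermometry

### Template shift fitting

The frequency of the ODMR dip is estimated by the interpolation method:

1. `build_template()` averages the entire record into one unit-mean
   spectrum, defined between grid points by piece-wise linear
   interpolation. The template is self-derived, so no parametric line-shape
   assumption enters the shift estimate.
2. `fit_shift_series()` splits the record into independent 400 ms bins
   (two duty cycles) and finds, per bin, the shift $\delta f$ minimizing
   the sum of squared residuals between the bin spectrum and the template
   evaluated at $f - \delta f$, with a free amplitude and offset per bin to
   absorb photoluminescence drifts (raw PL varies substantially inside
   cells). The search is a coarse grid at the 0.3 MHz grid spacing over
   ± a quarter of the sweep span, a fine grid at a tenth of the spacing,
   and a three-point parabola through the minimum — resolution well below
   1 kHz. Shifts beyond a quarter of the span are flagged out of range.
3. `average_shifts(n_f = 25)` averages non-overlapping blocks of $n_f$
   consecutive shifts, attaching the standard error of the block. The
   default, 25 bins = 10 s, matches the multi-minute temperature protocols
   used by the presets; it is fully configurable.
4. `shift_to_temperature()` divides by $\kappa$.

The per-bin least-squares standard error is first-order (a local quadratic
around the SSE minimum with a homoscedastic residual variance); on Poisson
data it runs some 20 % below the true scatter, which is why the pipeline's
error bars come from the block scatter in step 3, not from step 2.

### Sensitivity: Allan deviation against the Cramér–Rao bound

`allan_sensitivity()` computes the overlapping Allan deviation of the
temperature trace over half-octave accumulation times, finds the
white-noise region by sliding four-point log–log fits that accept local
slopes of $-0.5 \pm 0.1$, and reports
$\eta = \sigma_A(\tau)\sqrt{\tau}$ averaged over that region, in
K/√Hz. If no region qualifies the report is flagged and nothing is
extrapolated.

`cramer_rao_sensitivity()` computes the shot-noise limit for the same
spectrum model: the Fisher information for the dip centre from Poisson
counts, $I = \sum_i (\partial\lambda_i/\partial f_0)^2/\lambda_i$ per 2 ms
sweep, accumulated at 400 sweeps per second of wall-clock time (the 160/200
duty factor is what makes it 400 rather than 500), giving
$\eta_{\mathrm{CRB}} = 1/(|\kappa|\sqrt{I \cdot 400\,\text{s}^{-1}})$.

On a simulated 30-minute shot-noise-limited record the template fit reaches
this bound to well within 10 % (typically within a few per cent) — the
level of agreement expected of an efficient estimator, and the consistency
benchmark the test suite holds the thermometry chain to. Because the template is
itself built from the data, its residual noise is common to all bins and
can push the apparent long-$\tau$ Allan deviation slightly *below* the
white-noise line; the reported comparison therefore uses the magnitude of
the relative deviation.

### The reference thermometer

`generate_rtd_trace()` / `rtd_to_temperature()` implement the linear
resistive temperature detector used as the chip-level reference:
$R(T) = R_0(1 + \eta_{\mathrm{RTD}}(T - T_0))$ with
$\eta_{\mathrm{RTD}} = 2.44\times10^{-3}$/°C, and its exact inverse. Gold's
resistivity is linear over the relevant range, so nothing more elaborate is
needed.

## Rheometry

### MSD and its variance

`compute_msd()` is the time-averaged estimator
$\mathrm{MSD}(\tau) = K^{-1}\sum_i |\mathbf r(i+\tau)-\mathbf r(i)|^2$,
$K = N - \tau$, over a chosen axis set (transverse by default, matching how
the axial channel's higher noise is usually handled). Lags run to $N/4$;
beyond that too few pairs remain for the variance estimator's validity
regime. Long trajectories use a 150-point log-spaced lag grid.

Because overlapping pairs share underlying data, the time-averaged MSD has
inherent variance even without measurement noise. Per axis the package
estimates it from the empirical autocovariance $\hat C(m)$ of the squared
pairwise differences:
$$\widehat{\mathrm{Var}}[\mathrm{MSD}_x(\tau)] = \frac{1}{K}\Big[\hat C(0)
 + 2\sum_{m=1}^{\tau-1}\big(1 - \tfrac{m}{K}\big)\hat C(m)\Big],$$
valid for $\tau \ll K$, $K \gg 1$ (enforced as $\tau \le K/10$,
$K \ge 100$; out-of-regime lags are flagged, never silent). The three axes
are independent, so multi-axis variances add. Against a 500-trajectory
brute-force ensemble the estimator lands within
[0.8, 1.25] of the true variance at lags of 2–10 steps.

The combined error applies the noise-floor rule: whenever the statistical
error — or the MSD value itself — falls below
$10^{-4}\,\mu\text{m}^2$, the error is the noise floor.

### Diffusion, radius, moduli

`estimate_diffusion()` reads $D$ from the MSD at a single lag (1 s by
default, `MSD`/(2·d·τ)) or from a weighted line through the origin.
`stokes_einstein_radius()` fits $D(T) = k_BT/6\pi\eta(T)r$ with the radius
as the only parameter; since the model is linear in $1/r$ the weighted
solution is closed-form, and with 5 % noise on $D$ over six temperatures
the radius comes back within ±1 nm.

The viscosity model is linear and *decreasing* in temperature,
$\eta(T) = \eta_0 - 0.0208\,\text{Pa·s/°C}\,(T - 35°C)$ with
$\eta_0 = 0.301$ Pa·s for glycerol. A note on provenance: published
glycerol constants in this temperature range are not mutually consistent
(a fixed-viscosity reference of 0.919 Pa·s at 21 °C circulates alongside
these slope constants, and no sign convention reconciles all three
numbers), so `medium_model()` exposes $\eta_0$, the slope magnitude and the
anchor temperature as configuration rather than asserting one source; only
the slope's magnitude and the anchor value are treated as fixed points of
the model.

`mason_modulus()` converts the transverse MSD into the complex shear
modulus by the local power-law (Mason) form of the generalized
Stokes–Einstein relation. At each $\omega = 1/\tau$ (reported as
$f = \omega/2\pi$):
$$|G^*(\omega)| = \frac{2k_BT}{3\pi r\,\mathrm{MSD}(1/\omega)\,
 \Gamma(1+\alpha(\tau))}, \qquad \delta = \frac{\pi\alpha}{2},$$
with $G' = |G^*|\cos\delta$, $G'' = |G^*|\sin\delta$ and $\alpha(\tau)$
the local log–log slope of the MSD from a quadratic fit over a ±3-point
window in $\ln\tau$. The normalization and the $\omega = 1/\tau$
correspondence are fixed jointly by the viscous-limit identity: a
transverse MSD of $4D\tau$ with $D = k_BT/6\pi\eta r$ must give
$G''(f) = 2\pi f\eta$ exactly and $\delta = \pi/2$ — which the test suite
verifies analytically and on simulated trajectories (recovered $\eta$
within 5 %). Published renderings of the GSER prefactor vary with the
dimensionality of the MSD used; anchoring on the exactly-solvable limit
removes the ambiguity. Errors on $|G^*|$ propagate multiplicatively from
the MSD error, treating the error on $\alpha$ as negligible. Local
exponents are clipped to $[0,2]$ with a warning; noise-floor lags are
excluded.

### PSD and active forces

`welch_psd()` estimates one-sided position PSDs by Welch's method — Hann
window, 50 % overlap, mean-detrended segments of 28.8 s by default,
density-normalized so the integral recovers the signal variance (the
Parseval test pins this down). The installed `signal` package does not
provide a Welch estimator, so it is implemented here on `stats::fft` and
validated against the analytic Brownian $1/f^2$ tail. The value at the
40 Hz read-out frequency is taken from the nearest bin.

`decompose_forces()` applies Hooke's law in frequency space. With the
complex spring constant $K(\omega) = 6\pi r\,G^*(\omega)$, the measured
position PSD decomposes as
$$|K(\omega)|^2\,\langle x^2(\omega)\rangle =
 \langle \xi^2(\omega)\rangle + \langle F_\mathrm{ext}^2(\omega)\rangle,$$
where the thermal force term follows from the fluctuation–dissipation
theorem: per axis the thermal position PSD is
$S_\mathrm{th}(f) = (2k_BT/\pi f)\,K''/|K|^2$ (doubled to match the
two-axis transverse PSD), which reduces to the Brownian $D/\pi^2f^2$ per
axis in a viscous medium — an exact consistency anchor between the PSD,
modulus and force modules. The active-force PSD is the excess over the
thermal bound, clipped at zero with clipped points flagged. On
equilibrium simulations the excess is consistent with zero; injected
random kicks raise it monotonically.

## Motion classification

Directed-transport episodes are detected with the directionality ratio
$\gamma = d/l$ (net displacement over path length, transverse plane). The
null distribution of $\gamma$ for free diffusion has no convenient closed
form at finite window length, so `gamma_null_threshold()` builds it by
Monte Carlo with matched $D$, window and sampling period; the default
threshold is the 99th percentile over $10^4$ windows of 50 samples
(≈ 0.48 s). `segment_trajectory()` slides that window at stride 1, flags
exceedances, requires runs of at least 10 windows (merging gaps shorter
than 3) to suppress single-window flicker, and labels the remainder
nondirected. Per segment it reports $\gamma$ and a fitted exponent over
lags from 2 samples to a quarter of the segment length. On pure Brownian
input the per-window false-positive rate matches $1 - q$ and no long
directed segments survive the run-length rule; an inserted 5 s drift
interval is recovered with over 80 % overlap.

`fit_alpha()` is ordinary least squares of $\ln\mathrm{MSD}$ on
$\ln\tau$. Two estimator caveats are documented rather than hidden: the
log of a noisy MSD is biased slightly low (Jensen), giving ensemble-mean
exponents around 0.99 for truly Brownian input; and the regression SE
understates the true spread because MSD points at different lags are
strongly correlated. Log-spaced lag grids keep both effects small —
dense linear grids overweight the noisy long lags and roughly double the
bias. `summarize_alphas()` fits a maximum-likelihood normal to a sample of
exponents and reports sub/diffusive/super fractions, with a labelled
±0.1 band around 1 as reporting convenience.

## The end-to-end pipeline

`run_pipeline(run_config(preset, ...))` generates both raw streams on a
shared clock from a programmed temperature profile and runs both analysis
chains. Presets: `glycerol` (Brownian in glycerol, 3.5 °C steps every
5 min; diffusion tracks temperature through Stokes–Einstein, so the
temperature and viscosity channels anti-correlate), `gcx_like`
(subdiffusive fBm, $\alpha = 0.6$, cycled over a 10.6 °C span with a
larger MSD amplitude — hence lower $|G^*|$ — in the hot phase),
`cell_like` (Brownian with an inserted directed interval) and
`nocodazole_like` (fBm, $\alpha = 0.3$: the microtubule-depolymerized,
elasticity-dominated regime). The rheology channel is reported in 30 s
bins — $D$ and $\eta$ for glycerol, $|G^*|$ at ≈ 2.7 Hz for the
viscoelastic presets, PSD at 40 Hz for the cell preset — alongside the
$n_f$-averaged temperature trace; bins are left-closed, right-open,
labelled by the left edge. The two channels share nothing but the clock
and the programmed profile, which the independence test verifies by
perturbing one stream and asserting the other unchanged. Reports
serialize to JSON (`write_report()`), trajectories and ODMR streams to
CSV with JSON metadata sidecars, byte-identically reproducible from the
master seed.

```{r pipeline-example, eval = FALSE}
report <- run_pipeline(run_config("glycerol", duration = 600, seed = 1))
plot_temperature(report$temperature)
autoplot(report$sensitivity)
```

## Problem sizes and numerical choices

The test suite and the acceptance analyses use deliberately modest problem
sizes chosen to make Monte-Carlo error comfortably smaller than each
tolerance: 10 trajectories of $10^5$ steps for the MSD proportionality
constant (relative standard error ≈ 0.3 % against a 2 % tolerance), 100
trajectories of $10^4$ steps for exponent recovery, 500 trajectories of
$10^3$ steps for the variance-estimator benchmark, and a 30-minute ODMR
record (4500 bins) for the sensitivity comparison. Degenerate inputs are
defined, not rejected: $D = 0$ gives a stationary walk, $\kappa = 0$ is a
valid temperature-insensitive control in the generator (only the
*calibration* requires $\kappa \ne 0$), zero path length gives
$\gamma = 0$ flagged, a zero-contrast spectrum gives an infinite
Cramér–Rao bound reported as such. Ties in grid searches resolve to the
first minimum; the parabolic refinement is skipped at grid edges and the
bin flagged.

## Known limitations

* The GSER conversion assumes local power-law behaviour and loses accuracy
  at the ends of the lag range, where the local slope is estimated
  one-sidedly; mid-band values are the trustworthy ones.
* The per-bin shift SE is first-order; use block averaging for error bars.
* The Allan white-noise detector needs several octaves of flat
  $\sigma_A\sqrt{\tau}$; very short records (< a few minutes) may
  legitimately report no white-noise region.
* The tracker simulator linearizes the PSF response around small offsets;
  its error estimates are not meaningful once the particle approaches the
  lost-particle threshold.
* Exponent fits inherit the small Jensen bias of log-MSD regression
  (≈ −0.01 at the default sizes); ensemble comparisons should use matched
  fitting ranges.
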