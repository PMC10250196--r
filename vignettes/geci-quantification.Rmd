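---
title: "Models and methods behind gecilab"
author: "gecilab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gecilab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecilab)
```

`gecilab` characterizes genetically encoded calcium indicators (GECIs) and
converts their fluorescence into calcium signals. This vignette explains
the models each module implements, the assumptions they rest on, the
tunable parameters with their defaults, and the numerical and design
choices made where the underlying procedures are conventionally left
underspecified. Every empirical statement below is backed by a test in
`tests/testthat/`; the problem sizes quoted (seed counts, trace lengths)
are the ones those tests run.

## Chromophore photophysics

### Two-state model and the conservation relations

A GFP-like chromophore exists in a protonated neutral state N (absorption
band near 403 nm) and a deprotonated anionic state A (near 509 nm). With
total chromophore conserved during an H⁺ titration, and with the
alkaline-denatured form D (band near 447 nm) as a concentration anchor,

$$ n_D = n_A + n_N, \qquad n_X = \mathrm{OD}_X / \varepsilon_X, $$

so the slope $S = \Delta\mathrm{OD}_A/\Delta\mathrm{OD}_N$ of the anionic
band regressed on the neutral band across pH satisfies
$\varepsilon_A/\varepsilon_N = -S$, and

$$ \varepsilon_N =
   \frac{\mathrm{OD}_A/(-S) + \mathrm{OD}_N}{\mathrm{OD}_D/\varepsilon_D},
   \qquad \varepsilon_A = \varepsilon_N \times (-S), $$

with $\varepsilon_D = 44{,}000\ \mathrm{M^{-1}cm^{-1}}$ for denatured
green chromophores. State fractions follow as
$\rho_A = n_A/(n_A + n_N)$, and the pKa comes from fitting
$\rho_A(\mathrm{pH}) = 1/(1 + 10^{h(\mathrm{pKa} - \mathrm{pH})})$.

Assumptions: exactly two absorbing states plus the denatured form; full
denaturation at pH 12.5; a path length of 1 cm folded into the OD values.
The model carries no instrument correction and no spectral unmixing
beyond the two-band structure.

### Band quantification choices

* **Peak OD, not band integrals**, within fixed windows 380–430 nm
  (neutral) and 470–540 nm (anionic). Peak OD has the same units as the
  regression the slope feeds, and is robust after smoothing; integrals
  would need a bandshape model we do not assume.
* **5-point running-median filter** before peak-picking (raw peaks are
  retained as an attribute). The filter flattens a Gaussian-band peak by
  under 0.5% on a 1-nm grid; because the attenuation factor is identical
  for bands of equal width, it cancels exactly in the ε ratios — the
  round-trip tests recover ε to numerical precision despite it.
* **Baseline**: the mean OD over 600–650 nm, where protein chromophores
  do not absorb, is subtracted per spectrum.
* **Evaluation pH 7.2** by default — the standard measurement buffer pH —
  since the conservation relation must be evaluated at a single titration
  point; any pH present in the series can be selected.
* **OLS with free intercept** for the slope (OD_A on OD_N). OD_N is the
  lower-noise regressor in simulation, and plain least squares is the
  stated convention for this regression; each Ca²⁺ state is fitted as its
  own series, never pooled.

Degenerate inputs: constant OD_N across pH (e.g. a fully anionic protein)
is a degenerate-regression error; a non-negative slope violates the
two-state anticorrelation and is refused; a flat anionic-fraction profile
makes the pKa unidentifiable and yields a warning with `NA` rather than a
spurious fit.

### Quantum yield and two-photon cross-sections

The slope-ratio method computes
$\Phi = \Phi_{std} \times S_{protein}/S_{std}$ from total integrated
fluorescence versus absorbance slopes, with fluorescein in 0.1 M NaOH
($\Phi = 0.925$, anionic chromophore) and TOLLES ($\Phi = 0.79$, neutral
chromophore) as the bundled standards. Values above 1 are returned with a
warning, since they indicate a calibration problem, not a physical yield.

For two-photon measurements all system constants (pulse shape and width,
repetition rate, incident power, collection efficiency, refractive index)
cancel in the sample/standard ratio measured on the same rig, so the
cross-section needs only fluxes, concentrations, quantum yields and the
standard's cross-section. A fluorescein reference table (750–990 nm,
10-nm steps, linearly interpolated) is bundled; its values are
approximate (~10%) literature digitizations and can be overridden
per-wavelength.

## Ca²⁺ titration and kinetics

Free calcium in EGTA-buffered mixes follows the reciprocal-dilution
relation $[\mathrm{Ca}^{2+}] = K_d^{EGTA} \cdot f/(1-f)$ for Ca-EGTA
volume fraction $f$; the default $K_d^{EGTA} = 150$ nM corresponds to
pH 7.2, ~0.1 M ionic strength, 22 °C, and should be overridden when the
buffer differs. No multi-site Ca²⁺/Mg²⁺ competition is modeled.

Hill fits use the four-parameter specific-binding-with-Hill-slope form
with a free offset $F_{min}$. Initialization: plateaus from the 5th/95th
fluorescence percentiles, $K_d$ from the concentration nearest
half-range, $h$ started at 2; Levenberg–Marquardt least squares with
positivity bounds on $K_d$ and $h$. A fit whose $K_d$ lands more than
50-fold outside the sampled range is reported as unidentifiable — that is
what "all points on one plateau" looks like to the optimizer. The dynamic
range is computed from the fitted plateaus by default because raw
extremes inflate DR whenever the minimal fluorescence sits near the
background level; the raw version is available behind a flag that marks
its output.

Off-rates fit $F(t) = F_\infty + A e^{-k_{off} t}$, requiring at least 10
samples and two e-folds of observed decay; the half-time $\ln 2/k_{off}$
is attached. Noiseless recovery is exact to optimizer precision
(1e-6 in the tests); at 1–2% multiplicative noise the median errors over
50 seeds stay below 3% ($K_d$) and 5% ($k_{off}$).

## Trace statistics

$\Delta F/F_0$ uses the mean fluorescence over the baseline window; the
defaults follow the field's conventions — 1 s before stimulus onset for
in vivo recordings, 0.5 s for slice-style data. Peak search runs over a
6-s response window after onset (configurable; no standard exists). Peak
SNR divides the peak $\Delta F/F_0$ by the baseline SD of
$\Delta F/F_0$; on noiseless synthetic input the SD is zero and the SNR
is returned as `Inf` with a flag rather than an error, so batch pipelines
do not halt on clean simulations.

Half-decay times fit $A e^{-(t-t_{peak})/\tau} + c$ from the peak to the
end of the response window, with $A, \tau > 0$ bounds and $\tau$
initialized from the 1/e crossing. The estimate is invariant to amplitude
and offset in the noiseless limit. On a pure exponential the recovery is
exact to 1e-4; on transients generated with the double-exponential AP
kernel the finite rise time perturbs the early decay, and recovery is
within 1% instead.

Ratiometric traces interpolate both channels linearly onto the signal
grid over their overlap (no extrapolation) and divide samplewise; common
multiplicative artifacts cancel exactly, and anticorrelated
excitation-ratiometric channels amplify the response to $kj - 1$ when the
channels move $k$-fold up and $j$-fold down.

The responsive-cell test is the classical equal-variance two-sample
Student's t-test on per-trial stimulus versus baseline means, two-tailed,
at p < 0.01 (Welch available behind a flag). Its type-I error is nominal:
0.01 ± 0.005 over 10,000 null replicates in the acceptance suite.

## iPEAQ

Photochromism contrast — the fractional drop from the violet-elevated
fluorescence to the relaxed 488-nm level — is a ratio, so it is
independent of expression level and detector gain. The quantification
steps are: mean contrast over the complete pre-stimulus cycles → basal
[Ca²⁺] by analytic inversion of the contrast Hill curve → normalizing
factor $k$ = in vitro fluorescence at basal [Ca²⁺] / measured basal
fluorescence → $[\mathrm{Ca}^{2+}](t)$ by inversion of the fluorescence
Hill curve applied to $k F(t)$. Gain invariance is exact by construction
($k$ absorbs any common factor); the tests assert it to 1e-9.

Design choices, where the procedure is conventionally underspecified:

* **Level estimation.** The violet-epoch and relaxed levels are estimated
  as plateau segment means (second half of the epoch; final fifth of the
  relaxation window), not as the raw epoch maximum and window minimum.
  Extrema of 50–150 noisy samples are biased outward by roughly two
  noise SDs, which inflates the contrast and propagates into a severalfold
  basal [Ca²⁺] error at 2% sampling noise; segment means are unbiased and
  agree with the extrema exactly on clean plateaus. `robust = FALSE`
  restores the literal extrema.
* **Completeness.** A cycle is flagged incomplete when the mean over the
  final fifth of its relaxation window sits more than 5% of the total
  drop below the mean over the preceding fifth — i.e. it is still
  decaying. Incomplete cycles are excluded from the basal contrast.
* **Basal fluorescence** is taken from the final quarter of each
  pre-stimulus inter-cycle gap. Averaging whole gaps would include the
  relaxation tail, which biases the estimate upward by several percent at
  typical time constants; the final quarter of a gap of ≥ 5τ is settled
  to well under 1%.
* **Pre-stimulus truncation.** Basal cycles are detected on the trace cut
  at `stimStart`, so a stimulus transient can never contaminate the last
  relaxation window.
* **Inversion domain.** Hill inversions are analytic, clipped 0.5% from
  each plateau to bound error amplification; clipped samples carry an
  out-of-range flag, and a basal contrast at a plateau (e.g. the zero-Ca
  limit) is an explicit out-of-calibration error. Calibration
  concentrations must bracket the expected in-cell values.
* Samples under violet illumination (and within a configurable `settle`
  window afterwards, while the photochromic state relaxes) are returned
  as `NA` — fluorescence there does not report [Ca²⁺].

The violet-epoch duration (2.5 s) and cycle schedule are generator
configuration, not constants. The photochromic state-switching kinetics
themselves are not modeled; contrast is treated empirically.

## Tuning statistics

Per-trial response amplitudes are the mean of the top quartile
(⌈n/4⌉ largest samples) of $\Delta F/F_0$ in the 4-s stimulus window,
averaged over trials. Under additive Gaussian noise this estimator is
positively biased by $\sigma\,\phi(z_{0.75})/0.25 \approx 1.27\sigma$;
the test suite measures exactly that bias at the default 6-trial design,
so users can correct for it when comparing across noise levels.

OSI uses the $2\theta$ vector sum, which folds opposite drift directions
together; negative amplitudes are clipped to zero first because the
formula assumes non-negative weights. DSI compares the argmax direction
(ties resolved to the lowest angle, deterministically) with its opposite
on the same 8-direction grid — the raw direction grid is kept for both
indices rather than folding to orientations, since the doubling handles
either convention. Both indices are invariant under positive rescaling of
the tuning curve, and OSI is checked against an independent
complex-resultant oracle to 1e-12.

## Synthetic data: what it does and does not emulate

The generators produce: two-Gaussian-band protonation spectra (bands
parameterized by FWHM, default 25 nm — at this width cross-band
bleed-through is below 1e-3, which is what makes the tiny Ca²⁺-free
anionic band recoverable to 0.1%); log-spaced Hill titrations; single-
exponential decays; photochromic cycle trains with exponential
relaxation; AP-train transients from a peak-normalized double-exponential
kernel (rise 10 ms; half-decay presets 409 ms "fast" and 482 ms "slow");
and von Mises-tuned trial tables (8 directions × 6 trials × 4-s windows).
Noise is multiplicative Gaussian with a configured CV, reflecting
shot-noise-dominated imaging. All randomness is seeded, generators are
byte-deterministic given a seed, restore the caller's RNG state, and
return their ground truth.

What passing these tests shows: the estimators invert their stated
forward models at the stated noise levels. What it does not show:
robustness to bleaching, motion, neuropil contamination, non-Gaussian
photon statistics at low counts, instrument spectral distortion, or real
band shapes — none of which the generators model. Conclusions about real
recordings need the usual upstream corrections, which are out of scope
here (as are ROI segmentation and spike inference).

## Problem sizes and budgets

The test suite runs noiseless round trips plus Monte-Carlo checks at 50
seeds (fits), 100 seeds (SNR scaling, ε under noise), 200 seeds (untuned
OSI at 60 trials), 1,000 seeds (test power, amplitude bias) and 10,000
null replicates (type-I error); the whole suite completes in well under a
minute on a single core. These sizes were chosen so that the Monte-Carlo
standard errors are several times smaller than the tolerances they check.

## Known limitations

* The two-band spectral model ignores vibronic structure; strongly
  non-Gaussian bands will bias peak-based OD estimates.
* The EGTA constant is a single-condition default; real buffers need the
  appropriate constant for their pH, temperature and ionic strength.
* Prism-style "specific binding with Hill slope" offset handling is
  reproduced as a free-offset four-parameter Hill; other conventions
  (fixed zero offset) will differ in the fitted plateaus, not in $K_d$.
* iPEAQ assumes the calibration and the live recording share the sensor's
  photophysics (same illumination intensities and durations); a contrast
  calibration acquired under different light doses does not transfer.
* Peak $\Delta F/F_0$ is computed on the trial-averaged trace by default;
  per-trial peaks (systematically larger under noise) are available by
  running traces individually.
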