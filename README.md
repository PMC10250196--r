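# gecilab

Quantitative characterization of genetically encoded calcium indicators
(GECIs), and conversion of fluorescence into calcium signals.

Developing or deploying a GECI requires a chain of quantitative steps that
are usually scattered across spreadsheets and one-off scripts: extracting
chromophore photophysics from absorbance spectra, fitting Ca²⁺
dose–response and kinetic curves, turning ROI time series into response
statistics, and — for photochromic sensors — converting fluorescence into
absolute [Ca²⁺]. `gecilab` implements this chain as a tested R package,
together with a synthetic-data module that generates every input with
known ground truth, so each estimator ships with a round-trip validation.

## What it computes

**Chromophore photophysics.** GFP-like chromophores interconvert between a
protonated neutral state (absorbing near 403 nm) and a deprotonated
anionic state (near 509 nm). Because total chromophore is conserved during
an H⁺ titration, the regression slope *S* = ΔOD_A/ΔOD_N across pH fixes
ε_A/ε_N = −*S*, and the alkaline-denatured spectrum (ε_D = 44,000
M⁻¹cm⁻¹) anchors the absolute scale:

    ε_N = (OD_A/(−S) + OD_N) / (OD_D/ε_D),   ε_A = ε_N · (−S)

with state populations ρ_A, ρ_N and the pKa from the
specific-binding-with-Hill-slope sigmoid. Quantum yields follow the
slope-ratio method against fluorescein (Φ = 0.925) or TOLLES (Φ = 0.79);
two-photon action cross-sections are computed relative to a bundled
fluorescein reference (750–990 nm).

**Ca²⁺ titration and kinetics.** Free [Ca²⁺] in EGTA/Ca-EGTA mixes
(reciprocal dilution), Hill fits F([Ca]) = F_min + (F_max −
F_min)·[Ca]ʰ/(K_dʰ + [Ca]ʰ), dynamic range DR = (F_max − F_min)/F_min from
fitted plateaus, and single-exponential off-rates K_off.

**Trace statistics.** ΔF/F₀ = (F − F₀)/F₀ against a pre-stimulus baseline;
peak SBR; peak SNR = peak ΔF/F₀ / SD_baseline; half-decay time from an
exponential fit; ratiometric (signal/reference excitation) traces that
cancel motion artifacts; and the responsive-cell Student's t-test at
p < 0.01.

**iPEAQ — absolute [Ca²⁺].** Violet (405 nm) pulses superimposed on 488-nm
excitation produce photochromic cycles whose contrast
((F₀ − F_end)/F₀)_hv decreases with [Ca²⁺] but, being a ratio, is
independent of expression level and detector gain. Inverting an in vitro
contrast calibration yields the absolute basal [Ca²⁺]; matching the in
vitro fluorescence curve at that concentration to the measured basal
fluorescence yields the normalizing factor that converts the whole live
trace to [Ca²⁺](t).

**Tuning.** Orientation and direction selectivity (OSI via the 2θ vector
sum, DSI = (R_pref − R_opp)/(R_pref + R_opp)) from trial-structured
drifting-grating tables, with top-quartile response amplitudes.

## Worked example

```r
library(gecilab)

## chromophore photophysics from a synthetic pH titration
g  <- genPHSpectra(epsA = 64260, epsN = 21420, pka = 7.0, noiseCv = 0)
extinctionCoefficients(g$series, evalPH = 7.2)
#> ChromophoreParams @ pH 7.2
#>   S      = -3
#>   eps_A  = 64260 M-1 cm-1
#>   eps_N  = 21420 M-1 cm-1
#>   rho_A  = 0.6131  rho_N = 0.3869

## Ca2+ titration with 1% noise
curve <- fitHill(genTitration(fMin = 1, fMax = 103.3, kd = 200, h = 2,
                              noiseCv = 0.01, seed = 1))
curve@fit
#> HillFit (increasing): y0 = 1.046, yInf = 103.9, Kd = 201, h = 2.016

## iPEAQ: absolute [Ca2+] from a noisy live trace with unknown gain
truth <- ipeaqTruthCurves()
caGrid <- 10^seq(log10(2.5), log10(25000), length.out = 12)
cal <- fitCalibrations(caGrid, hillEval(truth$contrastCurve, caGrid),
                       hillEval(truth$fluorCurve, caGrid))
caF  <- function(t) 100 + 900 * (t >= 55) * (1 - exp(-(t - 55) / 2))
live <- genPhotochromic(caTruth = caF, gain = 2.5, noiseCv = 0.02, seed = 7)
q <- quantifyCalcium(live, cal, stimStart = 50, settle = 2.5)
round(c(basalCa = q$basalCa, k = q$k), 3)
#> basalCa       k
#>  99.759   0.400
```

The recovered basal [Ca²⁺] (99.8 nM vs 100 nM generated) is obtained
without knowing the detector gain (2.5 here); the release transient
averages 903 nM over the final 5 s against a same-window ground truth of
907 nM. The extinction coefficients come back exactly because the
noiseless round trip inverts the generating conservation relations.

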