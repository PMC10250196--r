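Package: gecilab
Title: Quantitative Characterization of Genetically Encoded Calcium Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative characterization of genetically
    encoded calcium indicators (GECIs) and for converting fluorescence into
    calcium signals. Estimates chromophore state populations, extinction
    coefficients, pKa, quantum yields and two-photon action cross-sections
    from absorbance and emission spectra; fits Hill dose-response curves,
    dynamic range and off-rate kinetics from in vitro Ca2+ titrations;
    computes dF/F0 trace statistics (peak signal-to-baseline ratio, peak
    SNR, half-decay time), ratiometric traces and a responsive-cell test;
    implements photochromism-enabled absolute calcium quantification
    (iPEAQ) by inverting dual Hill calibrations; and derives orientation
    and direction selectivity indices from trial-structured drifting-
    grating responses. A companion synthetic-data module generates every
    input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'hill.R'
    'photophysics.R'
    'fluorescein.R'
    'titration.R'
    'trace.R'
    'ipeaq.R'
    'tuning.R'
    'synth.R'
    'io.R'
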