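Package: pnmrlipids
Title: Quantitative 31P NMR Lipidomics: Simulation, Processing,
    Deconvolution and Lipid-Class Quantification
Version: 0.1.0
Authors@R:
    person("Core", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for quantitative one-dimensional 31P NMR
    lipidomics. Synthesizes free induction decays (FIDs) with realistic
    lipid-class structure (multi-resonance phosphatidylethanolamine,
    two-phosphorus cardiolipin, mass-dependent signal-to-noise,
    concentration-dependent shift drift, age-dependent
    phosphatidylcholine hydrolysis and adduct shift offsets), reads 1D
    Bruker directories and a JSON FID dump dialect, processes FIDs under
    quantitative conditions (exponential apodization, zero filling,
    Fourier transform, phasing, baseline correction, chemical-shift
    calibration), deconvolves overlapping resonances with Lorentzian,
    Gaussian or pseudo-Voigt lineshapes, assigns peaks to phospholipid
    classes through an interval-valued chemical-shift library, and
    reports class abundances as mol percent with signal-to-noise
    presence rules and sample-ageing quality-control diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
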