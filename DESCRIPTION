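Package: p53mdm2
Title: Kinetic and Thermodynamic Analysis of p53 Peptide Binding to MDM2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of coupled folding and binding of p53
    transactivation-domain peptides to the N-terminal domain of MDM2.
    Implements helix-coil two-state analysis of TFE titrations followed by
    circular dichroism, helicity estimates from mean residue ellipticity at
    222 nm and from NMR conformational shifts, single-exponential fitting of
    stopped-flow traces with pseudo-first-order analysis of observed rates,
    quadratic tight-binding analysis of fluorescence titrations, 1:1
    isothermal titration calorimetry isotherm fitting with dilution
    correction and thermodynamic decomposition, mass-action simulators of
    two-state, conformational-selection and induced-fit binding schemes, and
    free-energy-surface and helix-propensity analysis of peptide
    conformational ensembles. A synthetic-data generator produces every
    input type from known ground truth so all stages are testable by
    parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
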