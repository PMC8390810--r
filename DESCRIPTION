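Package: thzhdx
Title: Hydrogen-Deuterium Exchange Kinetics and Intensity-Ratio Statistics
    for Sub-Terahertz Perturbation NMR Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein backbone amide hydrogen-deuterium
    exchange (HDX) monitored by NMR peak intensities under a transient
    perturbation such as sub-terahertz irradiation or mild heating. Implements
    the two-state (Linderstrom-Lang) opening model with the EX2 limit, pH and
    Arrhenius scaling of the intrinsic chemical exchange rate, piecewise
    exposure protocols, methyl internal-standard normalisation, perturbed-to-
    control intensity ratios with signal-to-noise error propagation, and the
    one-sigma acceleration/deceleration classification rule. A seeded
    synthetic-experiment generator reproduces the statistical structure of the
    measurement (three-spectrum summation, concentration jitter, SNR-based
    residue selection), and helpers map per-residue calls onto a PDB structure
    via the temperature-factor column. All user-facing functions take and
    return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
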