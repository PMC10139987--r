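Package: hcvr
Title: Physiology-Based PK/PD Analysis of Opioid Effects on the
    Hypercapnic Ventilatory Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a physiology-based pharmacokinetic/
    pharmacodynamic model of opioid-induced respiratory depression. A
    two-compartment pharmacokinetic model with zero-order oral absorption
    supplies plasma concentration to a closed-loop model of the CO2
    chemoreflex (alveolar and tissue CO2 mass balances, brain-tissue
    effect-site PCO2, hinge-function ventilation) under dynamic end-tidal
    forcing. Per-run hypercapnic ventilatory response (HCVR) biomarkers
    (resting ventilation, resting end-tidal PCO2, ventilatory recruitment
    threshold, slope, and ventilation extrapolated to a PCO2 of 55 mmHg)
    are estimated by nonlinear least squares of the kinetic forward model,
    and their drug sensitivity is quantified with effect-compartment
    sigmoid EMAX models (potency C50 and hysteresis half-life). Includes a
    synthetic-trial generator with between-subject and within-subject
    variability for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
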