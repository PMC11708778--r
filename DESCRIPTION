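Package: enzmech
Title: Post-Processing Toolkit for QM/MM Enzyme Reaction Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis chain that follows quantum-chemical
    characterisation of an enzyme reaction mechanism: rigid-rotor/harmonic-
    oscillator thermochemistry from vibrational frequencies with a
    vibrational-temperature cutoff, assembly of per-stage Gibbs free-energy
    profiles from step energies with energetic-span identification of the
    rate-limiting barrier, per-residue electrostatic decomposition of the
    rate-limiting barrier with macrodipole-guided mutation proposals,
    stationary-state geometry analytics (distances, Buergi-Dunitz angles,
    hydrogen-bond scans, Kabsch superposition), and a distance-criteria
    selector for catalytically competent molecular-dynamics frames.
    Includes seed-deterministic synthetic-data generators so the full
    pipeline is testable without an electronic-structure or MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
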