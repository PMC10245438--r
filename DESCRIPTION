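Package: packinglens
Title: Crystal Packing Geometry, Interface Contacts, and Ensemble Metrics
    for Apolipoprotein E Self-Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural analysis of apolipoprotein E (ApoE) self-association
    from crystallographic and ensemble coordinate data. Reconstructs
    crystallographic dimeric units from unit-cell and symmetry-operator
    records, measures the inter-chain angle between principal axes of
    inertia and classifies T-shaped versus V-shaped packing, detects
    salt bridges, polar contacts and steric clashes at the
    self-association interface, computes helix kink angles, side-chain
    chi1 dihedrals and Kabsch-Sander secondary-structure content over
    multi-model ensembles, aggregates peptide-level hydrogen-deuterium
    exchange (HDX-MS) deuteration into residue-level uptake maps, and
    smooths static-light-scattering aggregation traces with a zero-phase
    low-pass filter. A synthetic-structure generator (ideal helices,
    dimers at prescribed angles, symmetry crystals, ensembles, HDX
    peptide sets, sigmoidal traces) makes every computation testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
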