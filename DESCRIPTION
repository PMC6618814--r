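Package: pepqa
Title: Quality Assessment of Peptide-Protein Docking Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess peptide-protein docking models against a
    reference (crystal) complex using the CAPRI peptide criteria: native
    contact recovery (fnat), ligand and interface backbone RMSD after
    Kabsch superposition, plus two side-chain-aware measures - interface
    side-chain RMSD (S-RMSD) and native hydrogen-bond recovery (fnat_hb)
    from a geometric, HBplus-style detector. Includes the four-class
    CAPRI quality classification, a parametric refined scheme that
    loosens backbone RMSD thresholds while capping S-RMSD, aggregation
    of computational alanine-scanning tables into per-residue hotspot
    hit-rate maps and recovery histograms, and a seeded generator of
    toy peptide-receptor complexes and perturbation ensembles so the
    whole pipeline is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
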