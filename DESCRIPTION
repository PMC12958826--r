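Package: spsmap
Title: Sequence, Structure and Equilibrium-State Analysis of the Yeast SPS Amino-Acid Sensor
Version: 0.1.0
Authors@R:
    person("SPS", "Maintainers", email = "spsmap@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the Saccharomyces cerevisiae SPS
    amino-acid-sensor complex (Ssy1-Ptr3-Ssy5) and related membrane
    receptors evolved from LeuT-fold transporters. Provides multiple
    sequence alignment conservation profiling and conserved-box detection,
    degenerate short-linear-motif (SLiM) scanning with ortholog-conservation
    filtering, typed noncovalent contact detection (salt bridges, hydrogen
    bond proxies, pi-pi stacking, hydrophobic and sulfur clusters) in
    AlphaFold-style structure models, mutation neighbourhood and
    protein-protein interface mapping, an eight-state alternating-access
    conformational-equilibrium signalling model with dose-response and EC50
    analysis, and seeded synthetic-data generators with machine-readable
    planted ground truth so that every stage can be exercised without
    network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
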