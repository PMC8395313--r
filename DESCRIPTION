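Package: helimode
Title: Membrane Binding-Mode Analysis for Helical Anticancer Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence amphipathicity profiling (Fauchere-Pliska hydrophobicity,
    Eisenberg hydrophobic moment, helical-wheel projection), Kabsch-Sander
    secondary-structure assignment from coordinates, trajectory-derived
    membrane metrics (peptide-bilayer distance, helix tilt, per-residue
    insertion depth), and classification of helical membrane-active peptides
    into three membrane binding modes (carpet-like surface-parallel, partially
    helical anchored, and upright antenna-like). Includes a seeded synthetic
    peptide-bilayer trajectory generator with known ground truth, multi-model
    PDB input/output, and a tidy pipeline from sequences or trajectories to
    binding-mode calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    Biostrings,
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
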