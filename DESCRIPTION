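Package: ligandqc
Title: Ligand Validation Metrics for Protein-Ligand Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validation metrics for ligands in protein-ligand crystal
    structures: selection of the ligand of interest from a coordinate file,
    masked real-space correlation to a ligand-omit ("direct") map and to the
    difference map, geometry Z-scores against a monomer restraint dictionary
    with sigma floors and the Z-worst summary, united-atom bad-contact
    counting, and percentile ranking of the four metrics against a reference
    corpus with a combined score. Includes a synthetic-complex generator so
    the whole pipeline runs offline, an occupancy-scan diagnostic, Q-Q
    analysis of difference-map residuals, an effective-resolution estimate,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
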