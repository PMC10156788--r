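Package: trpcquant
Title: Quantitative Analyses for TRPC5-Galpha(i3) Structure-Function Studies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantitative analyses
    used in structure-function studies of the TRPC5 ion channel and its
    direct activator Galpha(i3): single-channel idealization by the 50%
    rule with a filter-derived dead time and open-probability estimation;
    Hill fitting of one- and two-ligand dose-response data including the
    PIP2 x Galpha(i3) open-probability surface and the Galpha(i3)
    amplification-ratio analysis; a chelator equilibrium solver for free
    divalent-cation concentrations in recording solutions; three-cube FRET
    bleed-through correction, FRET ratio and effective efficiency;
    metadata-level sorting of C4 symmetry-expanded cryo-EM particles into
    subunit-occupancy patterns with RELION STAR input/output; and
    structural comparison metrics (Kabsch superposition RMSD,
    Shrake-Rupley buried interface area, domain rotation angles). A
    synthetic-data module generates inputs with known ground truth for
    every stage, so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
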