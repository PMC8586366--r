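Package: bindkit
Title: Ligand-Macromolecule Binding Analysis from Optical Titrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of small-molecule binding to DNA and serum albumin from
    optical titration experiments: Stern-Volmer fluorescence quenching (Ksv, Kq)
    with static/dynamic mechanism classification, double-log binding-site fits
    (Kb, n) and Gibbs free energy of binding, Job's method of continuous
    variation for stoichiometry, dye-displacement and viscometry evidence with a
    rule-based groove-versus-intercalation verdict, frontier-orbital global
    reactivity descriptors via Koopmans' theorem, and Lipinski rule-of-five
    evaluation. Includes seeded synthetic-data generators with known ground
    truth for every assay the package analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
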