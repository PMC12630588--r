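Package: cppaint
Title: Covalent Protein Painting Analysis of Lysine Solvent Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for covalent protein painting (CPP)
    experiments, in which exposed lysine epsilon-amines are dimethylated in
    vivo with a light isotope label and previously shielded lysines are
    labeled heavy after digestion, so that the light/heavy MS1 ratio of each
    peptide reads out per-residue solvent accessibility. The package converts
    measurement-level light/heavy peak areas into per-lysine accessibility
    summaries with quality-control filtering, reconciles forward and
    label-swap experiments, performs per-site one-way ANOVA across conditions
    with Benjamini-Hochberg or two-stage Benjamini-Krieger-Yekutieli FDR
    correction, computes rolling-probe solvent-accessible surface areas of
    lysine epsilon-amines from PDB structures and scores concordance between
    chemistry-derived and structure-derived accessibility, and generates
    seeded synthetic CPP experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
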