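Package: PhosCons
Title: Cross-Species Conservation and Structural Analysis of Phosphorylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers functionally important phospho-regulatory events from
    mass-spectrometry phosphosite catalogs. Compiles non-redundant phosphosite
    sets with localization-confidence filtering, predicts orthologs by
    reciprocal best hits over exact affine-gap alignment, calls per-site
    conservation across species with a +/-2 residue window, trains per-kinase
    position-specific scoring matrices scored with the Matrix Similarity Score
    and cross-validated AROC, lifts site predictions to kinase-protein
    interactions ranked by conservation degree, and quantifies phosphosite
    solvent-accessibility variability across comparative structure models. A
    seeded synthetic-cohort generator emulates every input so the full
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
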