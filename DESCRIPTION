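Package: rasflux
Title: Transcriptomics-Constrained Metabolic Flux Analysis, Sampling and
    Enrichment Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates gene-expression data into constraint-based metabolic
    models via Reaction Activity Scores (RAS) computed from gene-protein-
    reaction (GPR) boolean rules (OR as sum, AND as minimum). Normalized RAS
    values scale per-sample reaction bounds, and medium composition tables
    constrain exchange reactions. The constrained flux space is explored with
    flux balance analysis, parsimonious FBA, flux variability analysis,
    single-reaction deletion, corner-based sampling and artificial-centering
    hit-and-run sampling, all on a built-in bounded-variable simplex solver.
    Flux distributions are compared between sample groups with a two-sample
    test, a signed bounded fold change and a z-score, and the results are
    painted onto SVG metabolic maps. Models are read and written as SBML
    (Level 3 + fbc), COBRA-style JSON, YAML or a flat tabular schema.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
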