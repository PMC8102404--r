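Package: fluxlip
Title: Constraint-Based Flux Sampling, Metabolomics Statistics, and
    Lipid Chemoinformatics for Transporter Knockout Studies
Version: 0.1.0
Authors@R:
    person("J.", "Granath", email = "jgranath@example.org", role = c("aut", "cre"))
Description: Tools to study how loss of a membrane transporter reshapes
    systemic metabolism. Three analysis arms are provided: (1)
    condition-specific constraint-based metabolic modelling with
    hit-and-run flux sampling and per-reaction differential flux-state
    calling (F-test with fold-change filters, subsystem and metabolite
    roll-ups); (2) targeted metabolomics differential statistics
    (group-minimum imputation, Welch and Student t tests,
    Benjamini-Hochberg adjustment, Cohen's d, subpathway enrichment
    ratios, overlap with model predictions); and (3) chemoinformatic
    classification of elevated versus decreased lipids from SMILES
    structures using molecular descriptors, class balancing,
    leave-one-out validation, and a FreeViz-style projection. A
    synthetic-data module generates toy metabolic networks with planted
    knockouts, metabolomics tables with planted group effects, and
    two-class lipid structure sets so that every stage runs at desk
    scale with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
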