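Package: polyXnet
Title: Interaction-Network Analysis of Homopolymeric Amino-Acid Repeat Protein Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Proteome-wide analysis of proteins containing homopolymeric
    amino-acid repeats (AARs). Scans a proteome FASTA for maximal
    single-residue runs and defines the 20 polyX protein groups; extracts
    each group's protein-protein interaction network from a binary edge
    list and classifies edges as within-group (type a) or group-to-outside
    (type b); computes two connectivity indexes (type-a proportion and
    per-node type-a degree) normalized against equinumerous random control
    groups, with Yates chi-squared, one-way ANOVA, Dunnett many-to-one and
    Pearson correlation statistics; tests per-group protein-domain
    overrepresentation by hypergeometric tests with Benjamini-Hochberg
    control; and measures positional overlap of repeats and domains.
    Includes a planted-partition synthetic-data generator so the whole
    pipeline can be calibrated and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'polyXnet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'connectivity.R'
    'enrichment.R'
    'interactome.R'
    'overlap.R'
    'pipeline.R'
    'repeatScanner.R'
    'simulate.R'
    'statsTests.R'
    'utils.R'
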