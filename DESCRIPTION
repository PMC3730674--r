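Package: farm
Title: Constraint-Based Metabolic Modeling with Metabolite Dilution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constraint-based analysis of genome-scale metabolic
    models, centred on flux balance analysis with linear metabolite dilution
    (limed-FBA), one-LP functional pruning of blocked reactions (OnePrune),
    and evidence-weighted growth/no-growth reconciliation (CROP). Includes
    COBRA-dialect SBML import/export with a reversible identifier codec,
    gene-protein-reaction logic, media construction, gene essentiality and
    nutrient-rescue screens, genome-wide synthetic-lethal screening with
    mechanistic classification, and a generator of small synthetic networks
    (metabolic cycles, biosynthesis chains, alternate-route motifs) for
    testing every algorithm without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    pracma,
    boot,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
biocViews: Metabolomics, SystemsBiology, Network, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'build.R'
    'convert.R'
    'limedFBA.R'
    'crop.R'
    'farm-package.R'
    'media.R'
    'fixtures.R'
    'gpr.R'
    'lp.R'
    'oneprune.R'
    'phenotype.R'
    'sbml.R'
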