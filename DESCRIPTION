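Package: agecoal
Title: Coalescence Rate Inference from Genealogy-Dated Mutation Sharing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates pairwise coalescence rates through time between
    "target" and "reference" chromosome sets -- including low-coverage,
    unphased and ancient samples -- by recording whether mutations dated
    with a genome-wide genealogy are shared between the two sets, and
    maximising the resulting likelihood over piecewise-constant rates with
    an EM algorithm. Includes a self-contained pair-coalescent simulator
    with fixed-site augmentation, read-pileup emulation at arbitrary
    coverage, block-bootstrap confidence intervals, directional-migration
    mixture fitting by non-negative least squares, and trinucleotide
    mutation-spectrum statistics (relative rate curves, integrated mutation
    intensity, and a low-coverage TCC>TTC proportion estimator).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'timegrid.R'
    'mutations.R'
    'observations.R'
    'em.R'
    'simulate.R'
    'treeseq.R'
    'downstream.R'
    'mutspectrum.R'
    'agecoal-package.R'
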