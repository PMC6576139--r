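Package: namtools
Title: Simulation and Analysis of Nested Association Mapping Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and analysing nested association mapping
    (NAM) populations of recombinant inbred lines. Includes a forward
    simulator of single-seed-descent RIL breeding with Haldane crossovers,
    optional viability selection and array-genotyping artifacts; genotype
    quality control and per-family marker statistics; physical placement of
    array markers from alignment records; a signed, binned founder
    segregation-distortion scan; pairwise linkage disequilibrium with
    Hill-Weir decay fitting; neighbour-joining phylogenies and PCA;
    multi-environment trial BLUPs with broad-sense heritability; and a
    kinship mixed-linear-model association scan with principal-component
    covariates, Bonferroni QTN calling and gene-window lookup.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ape,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
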