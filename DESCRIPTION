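Package: egtscreen
Title: Phylogenomic Screening for Red-Lineage Genes in Green Secondary Phototrophs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting genes of cyanobacterial
    origin whose homologs in a green secondary phototroph (the
    chlorarachniophytes) affiliate with the red lineage (red algae and the
    CASH lineages) rather than with the Chloroplastida. Implements
    gap-fraction alignment trimming with a fallback threshold, species-level
    deduplication, topology-based filters for cyanobacterial origin (basal
    cyanobacteria, minimum OTU counts), a red/green affiliation classifier
    over bootstrap-annotated gene trees, exhaustive re-grafting of the
    chlorarachniophyte branch, and a from-scratch approximately unbiased
    (AU) test via multiscale RELL bootstrap of site log-likelihoods.
    Maximum-likelihood machinery (WAG+F+I+Gamma) is provided through
    'phangorn'. A sequence simulator generates gene families with known
    endosymbiotic or horizontal transfer histories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
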