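Package: flagscan
Title: Comparative Genomics of Flagellar and Chemosensory System Evolution
    in Actinobacteria
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rule-based detection and evolutionary analysis of bacterial
    flagellar and chemosensory systems from genome annotations. Implements
    flagellated-species calling from a 50-gene flagellar reference catalog
    (24-gene ancient core set), rod/hook paralog disambiguation by conserved
    gene order, four-state presence/absence matrices, chemosensory F-class
    and chemoreceptor heptad-class classification, GC-content screening of
    flagellar gene clusters for horizontal transfer, GGDEF-domain censusing
    with ecological group comparison, and species-tree/gene-tree concordance
    with inter-class transfer detection. Ships a seeded synthetic-genome
    generator with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    data.table,
    withr,
    ape,
    phangorn,
    phytools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: ComparativeGenomics, Phylogenetics, Annotation, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
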