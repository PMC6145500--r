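Package: milrscan
Title: Discovery and Target Analysis of microRNA-Like RNAs from Fungal Small RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained pipeline for discovering microRNA-like RNAs
    (milRNAs) in fungal genomes from small-RNA sequencing libraries, modelled
    on the workflow used for the basidiomycete Coprinopsis cinerea. It covers
    read preprocessing (quality filtering, adapter trimming, collapsing to
    unique tags), exact-match genome mapping, precursor-window extension and
    hairpin validation with an internal nearest-neighbor minimum-free-energy
    folding engine, a dinucleotide-shuffle randomization test, 95%-identity
    clustering and locus classification, three-mode consensus target
    prediction over 1000-bp downstream regions with expression-concordance
    filtering, hypergeometric term enrichment, seed-anchored homolog scanning,
    and comparative-Ct (delta-delta-Ct) quantification utilities. A synthetic
    data generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SmallRNA, Sequencing, GenePrediction, StructuralPrediction
RoxygenNote: 7.3.3
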