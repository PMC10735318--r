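Package: deepcne
Title: Detection of Regulatory DNA Conserved Across Distantly Related
    Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering gene-regulatory DNA segments that
    remain detectably similar across very distantly related animal
    genomes.  Conserved segments are found by calibrated local alignment:
    raw local-alignment scores are converted to E-values using Gumbel
    (Karlin-Altschul) statistics fitted on random sequences of matched
    nucleotide composition.  Candidate regions are masked against
    protein-coding, structural-RNA and pseudogene annotation, and the
    remaining conserved non-coding DNA is used as a reduced search space
    for cascaded cross-phylum searches, which multiplies sensitivity by
    the search-space reduction factor.  Hits are accepted either at a
    strict E-value threshold or at a relaxed threshold when the nearest
    genes on both sides are orthologs; a reversed (not complemented)
    genome serves as the negative control.  Accepted elements are
    classified as promoter, enhancer, intronic or 3'-UTR, their position
    and orientation relative to the nearest gene is tracked across
    species, and conserved regulatory "boxes" (CCAAT, E-box, CArG, Wnt
    response element) are detected in the cross-species alignments.  A
    synthetic-genome generator with planted ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
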