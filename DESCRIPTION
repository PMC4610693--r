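Package: motu454
Title: Species Delineation and MOTU Classification for 454 Amplicon
    Metabarcoding of the 18S V1-V2 Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for metagenetic species delineation from
    454-style pyrosequencing reads of the nuclear 18S rDNA V1-V2 region.
    Provides quality filtering with primer trimming, homopolymer run
    capping to correct pyrosequencing under- and over-calls, a greedy
    incremental identity-clustering engine with cd-hit semantics (de novo
    and reference-guided), similarity-threshold optimization against a
    Sanger reference library, residual MOTU clustering with a minimum-read
    rule and lowest-common-ancestor taxonomic assignment, community
    reproducibility statistics, and a calibrated 454-style read simulator
    with ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
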