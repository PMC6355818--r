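Package: famdup
Title: Duplication-Mode Inference for Expanded Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct how a gene family expanded within a genome.
    Harvests family members from a proteome by affine-gap similarity search,
    builds a neighbor-joining phylogeny from Poisson-corrected protein
    distances, detects tandem arrays from chromosomal gene order combined with
    tree sisterhood, calls segmental duplicate pairs from all-vs-all CDS
    identity at configurable thresholds, and infers retroduplication from
    Dollo reconstruction of intron presence together with poly(A)-tail and
    target-site-duplication scans of flanking sequence. Includes a scanner for
    light- and temperature-responsive promoter cis-elements and a forward
    simulator of family evolution that plants tandem, segmental and
    retroduplication events with known ground truth so every inference stage
    can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
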