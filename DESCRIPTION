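Package: probecap
Title: Capture Probe Design for Targeted Metagenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs hybridization-capture probe sets from an arbitrary
    collection of target gene sequences. Input sequences are clustered by
    greedy incremental clustering at a user-chosen identity threshold; each
    cluster receives group-specific probes selected by spaced-seed matching
    with a cross-cluster specificity check; clusters left without probes are
    rescued by multiple alignment, consensus calling and probe tiling; all
    probes are filtered on length, GC content and nearest-neighbor melting
    temperature, deduplicated, summarized, and annotated with the number of
    array synthesis cycles needed to manufacture them.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
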