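Package: hgtscan
Title: Horizontal Gene Transfer Detection by Phylogenetic Incongruence in
    Small Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects horizontally transferred genes in small, well-sampled
    microbial communities (such as acid mine drainage biofilms) from
    per-genome protein sets. Orthologous families are built by strict
    reciprocal-best-hit Smith-Waterman search, aligned progressively, and
    tested for incongruence with a reference organism tree using the
    approximately unbiased (AU) test with multiscale RELL bootstrapping
    under the Dayhoff substitution model. Families whose incongruence
    survives a rate-artifact filter based on bootstrap support are turned
    into donor/recipient transfer calls with direction, within-community
    flags and operon-like cluster detection. A forward simulator with
    planted transfer events and rate-shift decoys provides ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    Matrix
Config/testthat/edition: 3
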