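Package: coldcis
Title: Cold-Response Regulatory Genomics from Multi-Tissue RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline from a multi-tissue, multi-temperature
    RNA-seq count matrix to cold-responsive regulatory elements: RPKM
    normalisation and Fisher-exact differential expression for pooled
    single-library designs, fuzzy k-means co-expression clustering with
    correlation-based memberships, gene-length-aware GO enrichment via the
    Wallenius noncentral hypergeometric distribution, discriminative IUPAC
    promoter-motif discovery scored by one-sided Fisher exact tests with
    E-value correction, matching of discovered motifs to known
    transcription-factor databases, and assembly of a TF-gene interaction
    network.  A seeded synthetic-data module generates every pipeline input
    with planted ground truth so each stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
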