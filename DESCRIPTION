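Package: baculann
Title: Annotation and Comparative Genomics of Baculovirus Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating circular double-stranded DNA virus genomes and
    comparing them across isolates, built around the analyses typical of a
    nucleopolyhedrovirus (NPV) genome report: six-frame ORF prediction on a
    circular genome with a minimal-overlap resolution rule, classification of
    upstream regions by consensus baculovirus early (TATA + CAGT/CATT) and late
    ((A/T/G)TAAG) promoter motifs, detection of homologous regions (hrs) as
    clusters of near-palindromic repeat units with direct-repeat flanks,
    pairwise proteome comparison with identity-gene-parity plots and
    segmental-indel detection, scanning for transposon insertion signatures
    (perfect inverted terminal repeats with a TTAA target-site duplication),
    and absolute qPCR quantification of viral replication kinetics. A seeded
    synthetic-genome generator with full ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
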