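Package: netGBA
Title: Interactome Integration and Guilt-by-Association Dissection of
    Dietary Restriction Gene Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for network-based dissection of dietary restriction (DR)
    genetics: integration, identifier mapping, merging and evidence scoring of
    molecular-interaction data (PSI-MITAB and generic TSV); degree and
    interconnectivity statistics of seed gene sets; guilt-by-association
    prioritization of candidate genes with exhaustive leave-one-out
    validation; ortholog-presence and dN/dS conservation statistics with a
    degree/orthology/dN-dS multiple regression; replicate averaging,
    fold-change and two-fold differential-expression calling with
    hypergeometric set-overlap enrichment; transcription-factor target
    specificity and degenerate IUPAC motif enrichment in fixed-length
    promoters; expression-weighted interactome condensation into startup and
    shutdown networks; exact discrete-tail statistics and two p-value
    combination methods; and a synthetic-data generator that emulates the
    statistical structure of all inputs so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
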