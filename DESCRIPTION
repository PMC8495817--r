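Package: refbarcode
Title: Species Discrimination Analysis for DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating how well a DNA barcode reference library
    discriminates species. Implements all-to-all semi-global pairwise
    alignment with percent identity and query coverage, a best-match
    correct-assignment rule for singleton and multi-accession species,
    single-marker and combined-marker resolution summaries under complete and
    reduced samplings, supported-monophyly counting on bootstrap-annotated
    trees, assignment of amplicon sequence variants from bulk-sample
    metabarcoding with co-occurrence-based curation of erroneous variants,
    and a synthetic library and bulk-sample generator with ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
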