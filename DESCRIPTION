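Package: ampliref
Title: Curated Metabarcoding Reference Databases by In Silico PCR and
    Iterative Similarity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds curated, locus-specific reference barcode databases for
    metabarcoding studies. Discovers seed amplicons for a (possibly
    degenerate) primer set by in silico PCR against a local sequence
    collection, iteratively expands the seed set through taxonomically
    stratified similarity search, then dereplicates identical sequences and
    reconciles their taxonomy to the lowest common agreement before emitting
    a paired FASTA and taxonomy reference database. Includes a database
    comparison utility, an internal exhaustive search backend for fully
    reproducible offline runs, an adapter for external BLAST+ binaries, and
    a synthetic-fixture generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
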