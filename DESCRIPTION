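Package: varbrowse
Title: Backend for Population Variant-Frequency Browsers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable backend for browsing large population variant
    datasets. Ingests an annotated sites VCF (per-population allele counts
    plus a per-transcript consequence field), gene models in GTF, per-base
    coverage tables and side tables (constraint scores, CNV calls, rsID
    mappings); computes the gene-, transcript- and variant-level summaries a
    variant browser displays, including allele frequencies per continental
    group, the worst consequence across transcripts, same-codon
    multi-nucleotide variant candidates, exon coverage aggregation, CNV
    counts and deterministic selection of carrier samples for read-support
    display; and exposes them through a queryable store with search,
    autocomplete, region limits, CSV export and an HTTP-style request
    router. A seeded synthetic-fixture generator produces the full input
    bundle with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    callr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
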