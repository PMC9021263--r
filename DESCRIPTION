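Package: castsv
Title: Cas9-Assisted Targeted Nanopore Typing of Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves base-level breakpoints and genotypes of structural
    variants (SVs) discovered by whole-genome optical mapping, using
    Cas9-targeted nanopore sequencing. Provides SpCas9 guide-pair design per
    SV class (deletion, insertion, inversion), in-silico digestion and
    per-allele expected-fragment prediction, a seeded simulator of targeted
    amplicon reads with nanopore-like errors and truth alignments, and a
    breakpoint caller based on split-read and soft-clip analysis of
    alignments, including LINE-1 insertion typing against an element
    consensus and custom-reference validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    stats,
    utils,
    yaml
Suggests:
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
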