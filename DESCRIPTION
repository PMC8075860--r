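Package: tandup
Title: Detection and Quantification of Internal Tandem Duplications in
    Amplicon Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, annotates and quantifies internal tandem duplications
    (ITDs) in targeted amplicon deep-sequencing reads, such as those covering
    the FLT3 juxtamembrane region in acute myeloid leukemia. Reads are
    quality-filtered, collapsed to unique sequences, aligned semi-globally to
    the wild-type amplicon with affine gap penalties, and insertions are
    verified as tandem duplications against the reference. Per-clone output
    includes insert sequence, length, insertion site, trailing status,
    supporting reads, coverage, variant allele frequency (VAF) and allelic
    ratio (AR). Clones can be tracked across serial samples for measurable
    residual disease monitoring. A deterministic read simulator (wild-type
    and ITD alleles, count-exact mixtures, dilution series, substitution
    error model) makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    methods,
    generics,
    ggplot2,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
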