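Package: polr3class
Title: Pol III Type-3 Promoter Detection and Host-Gene Context
    Classification for Non-Coding RNA Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decides whether a non-coding RNA gene (such as the RNA subunit
    of RNase P or RNase MRP) is an independently transcribed RNA polymerase
    III unit or a promoterless gene embedded in an intron of a polymerase
    II-transcribed host gene. Builds species-specific position weight
    matrices for the proximal sequence element (PSE) and TATA box from
    U6/7SK promoter training sequences, scans candidate loci for a
    positionally constrained TATA box, a PSE, a 3' poly-T terminator and
    internal A-box/B-box elements, resolves each locus against a gene
    annotation (intergenic versus intronic, recipient gene, intron ordinal,
    orientation, tandem copies), and combines promoter evidence with
    genomic context into a per-locus and per-species classification.
    Includes read-density fold-enrichment analysis of intronic ncRNA
    expression, IUPAC signature-motif validation of candidate RNAs, and a
    seeded synthetic-species generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    graphics,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
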