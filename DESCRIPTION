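Package: hybridex
Title: Cis- and Trans-Regulatory Divergence from Hybrid Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for dissecting gene-regulatory divergence between two
    parental genotypes using F1 hybrid transcriptomes. Implements competitive
    allele-specific read assignment from paired alignments against the two parental
    references, negative-binomial Wald contrasts (including the joint parental/allelic
    model that estimates trans effects), classification of expression inheritance and
    of cis/trans regulatory divergence (with a dedicated scheme for hemizygous-X genes
    in males), chromosome- and gene-set-level Fisher enrichment with a dual
    significance rule, coding-sequence divergence (Ka, Ks, effective number of codons,
    codon-usage-corrected Ks'), upstream-window conservation scores, and K-means
    co-expression clustering. A synthetic-data module generates every input type with
    known regulatory ground truth so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
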