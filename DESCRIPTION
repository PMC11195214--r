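Package: rnachase
Title: RNA Stability and Splicing Dynamics from Metabolic-Labeling Chase Experiments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of nascent-RNA labeling/chase sequencing experiments
    (Bru-seq style 0h label plus timed uridine chases). Classifies aligned
    paired-end fragments into RNA classes (exonic, intronic, antisense,
    intergenic, ambiguous), computes strand-specific fractional feature
    counts and relative class stabilities, an intron-centric splicing index
    from junction reads, exon-spanning all-or-none splicing-pattern bins,
    per-gene relative stability (log2 fold change) over successive chase
    intervals with median-of-ratios normalization and a negative-binomial
    Wald test, and transcript-isoform dynamics via equivalence-class EM with
    dominance-trajectory classification. Ships a generative simulator of
    labeled RNA cohorts (biphasic decay, co-transcriptional and all-or-none
    splicing, isoform-specific turnover, paired-end fragment sampling) so
    every stage is verified by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
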