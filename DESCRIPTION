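Package: repurposeR
Title: Detection and Characterization of Enhancer-to-Promoter Repurposing
    Between Species
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative regulatory genomics toolkit for detecting
    orthologous loci that act as enhancers in one species and as promoters
    of stable transcripts in a sister species (P/E elements), polarizing
    the direction of the activity switch with an outgroup, and
    characterizing the sequence (GC/CpG) and motif (U1 splice-donor /
    polyadenylation-signal) changes that accompany it. Includes
    promoter/enhancer/inactive-region annotation from harmonized peak
    sets, interval projection through co-linear orthology block maps with
    reciprocal filtering, contingency statistics for regulatory turnover,
    a composition-shift resampling test against inactive-region nulls,
    TSS-anchored motif density profiling, and a deterministic synthetic
    clade generator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Epigenetics, ComparativeGenomics, FunctionalGenomics,
    SequenceMatching, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
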