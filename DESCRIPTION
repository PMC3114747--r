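Package: subcloneCNA
Title: Copy-Number Aberration Calling in Heterogeneous Tumor Samples via
    Allelic Imbalance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the copy-number status (gain, loss or normal) of the
    dominant aberrant subclone in heterogeneous tumor samples from aggregate
    B-allele-frequency and log-R-ratio signals. Implements a windowed
    trigonometric measure of allelic imbalance (the M-measure) with a
    three-state classifier and an optional three-state Viterbi decoder, a
    ground-truthed simulator of stroma/subclone mixtures on SNP-array-like
    signals, a linear-algebra solver for the stromal mixing coefficient at
    deletion loci, an exhaustive enumerator demonstrating the non-uniqueness
    of subclone de-mixing for three or more components, a three-class
    balanced-accuracy scorer, and a within-exon allelic-imbalance scanner for
    subclonal markers in RNA-seq count tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
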