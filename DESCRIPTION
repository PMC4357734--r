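Package: uvtx
Title: Simulation and Analysis of UV-Induced Transcription Inhibition and
    Recovery from Nascent RNA Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how ultraviolet-light-induced transcription-blocking DNA
    lesions suppress nascent RNA synthesis in a gene-length-dependent way and
    how synthesis recovers in the 5' to 3' direction under transcription-coupled
    and global-genomic nucleotide excision repair. Provides a mechanistic
    simulator of bromouridine-labeled nascent RNA (Bru-seq-like) coverage
    tracks with Poisson placement of photolesions, permanent polymerase arrest
    and genotype-specific repair kinetics; TSS-anchored metagene profiling,
    RPKM fold-change classification and a percent-recovery statistic; and the
    long-range qPCR zero-class (Poisson) lesion-frequency estimator with a
    matched fluorescence simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
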