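Package: nucfoot
Title: In Vivo MNase Footprinting Analysis of the Bacterial Nucleoid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of in vivo micrococcal nuclease (MNase) digestion of the
    bacterial nucleoid from aligned 5'-end sequence tags. Estimates the
    characteristic protected-fragment size by strand cross-correlation and the
    spacing periodicity of protected fragments by same-strand auto-correlation
    followed by Fourier analysis; computes strand-oriented metagene profiles of
    digestion-fragment centers, GC content and A-tract frequency around
    transcription start and end sites; calls clusters of digestion-resistant
    fragments from a Gaussian kernel density against a randomization null with
    empirical false discovery rate control and control-sample enrichment
    filtering; and computes A-tract (poly(dA:dT)) sequence statistics including
    genome-to-random ratios over shuffled genomes. A synthetic-data generator
    produces genomes, gene annotations and nucleoid/control tag sets with
    planted footprints, spacing periodicity, promoter A-tract enrichment and
    ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
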