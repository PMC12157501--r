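Package: noncanomiR
Title: Discovery and Classification of Noncanonical Small-RNA Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for classifying small-RNA loci by
    biogenesis pathway. Combines spike-in normalized differential abundance
    across Microprocessor, Dicer and RNA polymerase III depletion
    experiments with hairpin structural classification (stem base-pair
    counting on dot-bracket structures, with a built-in base-pair
    maximization folder), Pol III type-II promoter architecture scanning
    (Box A / Box B internal promoter motifs and poly-T terminators),
    untemplated 3' tailing and trimming-isoform analysis, and
    Microprocessor cleavage-efficiency scoring. Includes a synthetic
    small-RNA-seq data generator with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
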