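Package: modeg
Title: Multi-Organ Transcriptome Deregulation Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of transcriptional deregulation across
    several organs from per-gene expression ratio tables. Classifies genes
    as induced or repressed at a fold-change threshold, quantifies
    cross-organ concordance against an independence model, clusters organs
    by expression-ratio correlation with cophenetic robustness testing,
    tests gene panels for deviation from the genome background, scans
    chromosomes for deregulation bias and positional clusters with sliding
    windows, compares promoter transcription-factor binding-site counts
    between extreme induced and repressed genes, and validates array
    ratios against qPCR by the 2^-ddCt method. Includes a seeded
    synthetic-data generator emulating a five-organ intrauterine growth
    restriction study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    ape,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
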