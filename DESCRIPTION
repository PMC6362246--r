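Package: larvaseq
Title: De Novo Larval Transcriptome Reduction and Stage-Wise Expression
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing de novo assembled larval transcriptomes
    without a reference genome: stop-codon-to-stop-codon coding-region
    extraction, greedy identity clustering with iterative end-overlap
    consensus merging for redundancy reduction, similarity-based
    contaminant filtering, differential expression between developmental
    stages by a negative-binomial exact test at fixed dispersion,
    expression-profile clustering with transcription-factor and GO
    retention rules, hypergeometric GO term enrichment without ancestor
    propagation, and transition/transversion and density summaries of
    transcriptome polymorphisms.  A synthetic-data generator produces
    every input with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
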