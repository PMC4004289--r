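Package: codonContext
Title: Condition-Specific Codon Context Matrices and Probabilistic Gene
    Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds codon usage tables and 61x61 codon-pair context
    matrices from condition-specific gene sets (for example the most
    highly expressed or most differentially upregulated genes of a
    growth condition), probabilistically back-translates target
    proteins into codon-optimized DNA variants that follow the
    condition's codon-pair bias, and quantifies codon-usage drift
    between conditions with the Frobenius norm of matrix differences,
    including random-subsampling drift curves fitted with a power
    regression. A synthetic genome and expression-table simulator with
    known codon-pair structure supports end-to-end validation of the
    whole workflow without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, SequenceAnalysis, GenePrediction
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
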