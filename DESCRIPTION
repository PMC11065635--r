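Package: trnapool
Title: Cell-Type-Specific tRNA Pool Quantification and Codon Demand Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell-type-specific tRNA expression from RNA polymerase III
    ChIP-seq read counts and relates the tRNA supply to codon demand in matched
    translatomes. Provides gtRNAdb-style tRNA gene name parsing, occupancy
    classification, relative expression at gene, identical-transcript-group,
    isoacceptor and isotype resolution, pool-diversity metrics, variance-gated
    differential expression with Benjamini-Hochberg control, expression-weighted
    codon usage from CDS and TPM tables, permutation tests for codon enrichment in
    cell-type-specific gene sets, the tRNA-supply/codon-demand ratio, and a
    synthetic-data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
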