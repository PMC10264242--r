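Package: riboapa
Title: Differential Translation Efficiency and Poly(A)-Site Usage from
    Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical tests for ribosome profiling and 3'-end RNA-seq
    count tables. Models translation efficiency as the odds of drawing a
    ribosome-protected-footprint read versus an RNA read and tests
    per-transcript translation-efficiency ratios (TER) across arbitrary
    sample designs by binomial logistic regression, with optional
    correction of codon-level ribosome-stalling bias via deterministic
    local (loess-style) smoothing. Tests differential poly(A)-site usage
    per transcript by baseline-category multinomial logistic regression in
    overall, versus-reference and pairwise modes, reporting logAPAR (log
    fold change in proximal-to-distal site usage). Includes median-of-ratios
    library-size normalization, equally-populated-bin target-set enrichment
    with hypergeometric or logistic tests and permutation mutual-information
    z-scores, seeded synthetic-data generators with known ground truth, and
    a file-based command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
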