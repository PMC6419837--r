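Package: smilesbench
Title: Coverage Benchmarks for SMILES Generative Models on Enumerated
    Chemical Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how completely and uniformly a SMILES-based generative
    language model reproduces a finite, exhaustively enumerated chemical
    space. Provides a toy GDB-like enumerator with explicit chemical
    filters, a SMILES tokenizer, a from-scratch GRU sequence model fitted
    by teacher forcing ('smiles_lm'), closed-form ideal-model baselines
    from the coupon-collector problem, negative log-likelihood training
    diagnostics based on Jensen-Shannon divergences, sample partition and
    coverage reports, multi-model frequency spectra against a binomial
    null, violation labelling of out-of-space molecules, and MQN/PCA
    chemical-space maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
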