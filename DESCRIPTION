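Package: egscore
Title: Ensemble-of-Gene-Sets Senescence Scoring for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds driver-gene-conditioned up/down gene-set pairs from a
    reference single-cell RNA-seq dataset of replicative senescence, scores
    cells by a signed-extremum ensemble rule (mean z of upregulated genes
    minus mean z of downregulated genes per pair, aggregated by signed
    absolute maximum), classifies senescent cells with a two-Gaussian
    decision threshold and p21/p16 gating, and transfers the trained scorer
    to new tissues with re-derivation of tissue-specific markers. Includes a
    negative-binomial synthetic scRNA-seq generator with planted driver
    subpopulations, cell-cycle structure and ground truth for every
    recovery test, plus Matrix Market / GMT / TSV readers and writers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
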