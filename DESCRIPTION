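Package: cernanet
Title: Construction and Cross-Cancer Comparison of Competing Endogenous RNA Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA) regulation from
    miRNA-target predictions and expression profiles. Enumerates putative
    ceRNA pairs from a gene-by-miRNA targeting matrix, quantifies four
    regulation-strength factors per pair (shared-miRNA program size, binding
    site count, miRNA program expression, ceRNA expression state), compares
    correlation distributions across factor strata with two-sample
    Kolmogorov-Smirnov tests, selects optimal ceRNA pairs, builds the optimal
    ceRNA network with hub statistics, and compares core ceRNA networks
    across expression datasets. Includes a synthetic-data generator with
    known shared-miRNA coupling for end-to-end validation, TSV/SIF/GMT
    readers and writers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
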