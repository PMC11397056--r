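Package: evmirnet
Title: miRNA-mRNA Co-Expression Analysis for Uterine-Fluid Extracellular-Vesicle Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microRNA profiles measured in extracellular
    vesicles of bovine uterine lumen fluid alongside mRNA profiles from
    conceptus and endometrial tissue. Provides low-count filtering, trimmed
    mean of M-values (TMM) normalization with counts-per-million and an
    inverse-hyperbolic-sine transform, differential abundance calling from the
    consensus of a conditional negative-binomial exact test and a
    negative-binomial Wald test, all-pairs miRNA-mRNA Pearson co-expression
    with a permutation-based empirical false discovery rate, integration of
    predicted miRNA target tables for inverted-correlation pairs, and
    hypergeometric category enrichment with Holm family-wise error control.
    A negative-binomial synthetic-data generator with planted effects makes
    every stage testable without access to deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    edgeR
Config/testthat/edition: 3
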