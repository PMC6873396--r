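Package: tacitus
Title: Collection, Selection and Cross-Platform Integration of Transcriptomic Datasets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for managing and integrating bulk transcriptomic expression
    datasets. Reads GEO-style series-matrix files, MAGE-TAB (SDRF plus data
    matrix) archives and platform annotation tables; stores datasets in a
    file-backed repository with a sample index, a metadata index and a native
    full-text index for sample search; extracts sample selections by streaming
    the stored matrix one probe row at a time; maps probe identifiers to
    gene-level identifiers with configurable many-to-one collapse policies;
    combines selections across platforms with mean-centering, per-gene
    standardization, empirical-Bayes batch correction (ComBat) or
    cross-platform block normalization (XPN); and benchmarks the integration
    algorithms on simulated microarray and RNA-seq datasets with known
    differentially expressed genes, scored by a moderated-t test and ROC/AUC.
    A command-line entry point ties the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
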