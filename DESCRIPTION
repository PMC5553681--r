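Package: mirpassage
Title: miRNA Microarray Analysis of Multipotent Stromal Cells Across Culture Passages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-color miRNA microarray experiments on
    bone-marrow-derived multipotent stromal cells (MSCs) expanded across culture
    passages. Implements quantile and 75th-percentile normalization of probe-level
    signals, negative-control-based background cutoffs and detection calls,
    outlier-array flagging, a four-stage variability/magnitude filter cascade
    (within-chip, between-chip, biological variability, magnitude of expression),
    repeated-measures ANOVA with a compound-symmetry correlation structure and
    Benjamini-Hochberg-adjusted pairwise passage contrasts, pooled-variance group
    contrasts (e.g. MSC versus cancer lines), and an RT-qPCR confirmation arm with
    geometric-mean reference normalization. A synthetic-data generator emulates the
    repeated-measures study design with known ground truth so the full pipeline can
    be exercised and calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nlme,
    stats,
    utils
Suggests:
    ggplot2,
    limma,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
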