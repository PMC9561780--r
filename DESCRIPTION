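Package: stereoscape
Title: Spatial Transcriptomics Tumor-Microenvironment Analysis for Cervical Squamous Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational steps of a combined
    single-nucleus RNA-seq and sub-micron spatial transcriptomics study of
    cervical squamous cell carcinoma: aggregation of capture spots into
    square bins with chip geometry and bin-level quality control, gene
    signature scoring by control-matched module scores and a rank-based
    single-sample enrichment statistic, composite metabolic scoring and
    rank-based hyper/hypometabolic tumor classification, hypergeometric
    multimodal intersection analysis (MIA) with a joint marker-expression
    gate for myofibroblastic cancer-associated fibroblast (myCAF) regions,
    Wilcoxon rank-sum differential expression with fold-change and
    expressed-fraction filters, HPV positivity calling from per-base viral
    genome coverage, and composite immunohistochemistry scoring with
    contingency-table association tests. A synthetic-data module generates
    spot-level chips, labeled cell matrices, viral depth profiles, and IHC
    cohorts with planted structure so the whole pipeline is testable
    without access to the original tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
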