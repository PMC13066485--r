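Package: fuzzyagree
Title: Paired-Assay Agreement Statistics and Cluster-Generated Fuzzy
    Inference for 25(OH)D Method Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Method-comparison toolkit for paired clinical assay results,
    built around serum 25-hydroxyvitamin D measured by chemiluminescence
    immunoassay (CLIA) and liquid chromatography-tandem mass spectrometry
    (LC-MS/MS). Provides the full paired-agreement battery (intraclass
    correlation from one-way mean squares, Bland-Altman limits of
    agreement, paired t-test, comparison regression, threshold
    cross-classification with Cohen's kappa and Wilson score intervals,
    multi-threshold reclassification), a fuzzy C-means clusterer and a
    cluster-generated Takagi-Sugeno fuzzy inference system mapping
    (CLIA, LC-MS/MS, sex, age) to the inter-method difference, a
    relative-risk verification stage for demographic subgroups, and a
    synthetic paired-cohort generator reproducing the statistical
    structure of a 25(OH)D comparison study so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
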