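Package: crcsubtype
Title: Molecular Subtyping and Dose-Response Analysis for Colorectal Cancer Preclinical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular characterization of colorectal cancer (CRC)
    preclinical model systems (2D monolayer cultures, 3D spheroids, and
    xenograft tumors). Implements quantile-rank-based single-sample scoring
    and nearest-template prediction for the intrinsic epithelial consensus
    molecular subtypes iCMS2 and iCMS3, differential-expression filtering and
    expression-pattern taxonomy across model systems, hierarchical clustering
    and model-system similarity analysis, four-parameter logistic (4PL)
    dose-response fitting with IC50 estimation from bioluminescence spheroid
    cytotoxicity assays, and Welch comparison of IC50 values between assay
    formats. A synthetic-data generator with planted ground truth makes every
    stage testable without access to external microarray or plate data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
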