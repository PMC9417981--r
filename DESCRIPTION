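Package: dfnmrd
Title: Standardized LAIP-Based Different-from-Normal MRD Detection for AML Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a standardized one-tube, fixed-gate, LAIP-based
    different-from-normal (DfN) algorithm for flow-cytometric measurable
    residual disease (MRD) detection in acute myeloid leukemia. Provides
    hierarchical gating of compensated event data into 8 myeloid
    progenitor/monocyte main populations and 32 aberrant subpopulations,
    nonparametric reference-value estimation from leukemia-free control
    cohorts with cohort attribution, MRD calling with origin classification
    (aLAIP vs post-treatment DfN) and alternative calling schemes (ELN 0.1%
    cutoff, load split, immature-only), Krippendorff's alpha for inter-rater
    reliability, and a synthetic bone-marrow simulator with exact ground
    truth for validation without patient data. Reads FCS 3.0/3.1 files and
    plain CSV event tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
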