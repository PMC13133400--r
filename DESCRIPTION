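Package: balanceCPM
Title: Connectome-Based Predictive Modeling of Balance Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of postural balance
    from structural and functional brain connectomes. Implements edgewise
    partial Spearman feature selection with covariates, leave-one-out
    cross-validated linear prediction, stability-aware p-value threshold
    search, permutation-based model significance with Benjamini-Hochberg
    correction across model families, consensus-connectome extraction with
    canonical-network summaries, combined multimodal models, external
    (test-retest) validation and behavioral specificity tests. Includes
    posturographic sway-area computation (95% confidence ellipse of the
    center-of-pressure trajectory) and a synthetic cohort generator with
    planted edge-behavior effects for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
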