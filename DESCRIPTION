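Package: nichecast
Title: Maximum-Entropy Niche Models, Climate Scenario Projection and
    Range-Shift Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Presence-background species distribution modelling with a
    regularized maximum-entropy (Gibbs) model built from linear, quadratic,
    product and hinge features. Covers the full analysis chain: occurrence
    record cleaning and spatial thinning, collinearity-based predictor
    selection (pairwise correlation / variance inflation factor pruning and
    preliminary-model contribution pruning), candidate-model calibration by
    partial-ROC significance, omission rate and AICc, bootstrap replicate
    fitting, projection onto climate scenario layers with clamping,
    mobility-oriented parity extrapolation maps, threshold-based binary
    range maps, habitat change and centroid range-shift summaries, and
    protected-area overlap accounting. Includes a seeded synthetic-landscape
    generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    mgcv,
    geosphere,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
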