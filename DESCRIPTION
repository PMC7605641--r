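Package: ratfc
Title: Preprocessing and Functional Connectivity Analysis for Awake-Rat
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible preprocessing and analysis pipeline for
    resting-state BOLD fMRI acquired in awake rats. Implements framewise
    displacement motion scrubbing, intensity-based rigid-body motion
    correction, per-scan spatial ICA with feature-based noise-component
    classification adapted to the rat brain, Monte-Carlo CompCor nuisance
    selection, soft (shared-variance-preserving) noise removal, Gaussian
    smoothing and zero-phase Butterworth band-pass filtering, and
    group-level connectivity analyses: ROI functional-connectivity
    matrices with mixed-model inference and max-statistic permutation
    familywise error control, seed maps, structure-function comparison,
    reproducibility metrics, group ICA with Ward module detection, and
    SNR quality control. A synthetic phantom generator with full ground
    truth makes every stage testable without real acquisitions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
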