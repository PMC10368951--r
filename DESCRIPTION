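Package: attnfuse
Title: EEG Attention-State Recognition by Fused Time, Frequency and
    Non-Linear Dynamics Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for recognising attention versus
    non-attention states from multichannel scalp EEG. Provides a
    paradigm-faithful synthetic-EEG generator, FIR band-pass
    preprocessing with epoch segmentation and artifact rejection, a
    123-dimensional per-channel feature fusion (12 time-domain, 48
    frequency-domain and 63 non-linear-dynamics features including
    Hjorth parameters, wavelet sub-band energies, Teager-Kaiser energy
    and a family of entropies and fractal dimensions), chronological
    5-fold and leave-one-subject-out cross-validated classification
    with random forests, decision trees and linear SVMs, and
    group-level statistics (paired feature t-tests, FDR-corrected
    band-limited connectivity contrasts, Z-scored band-power
    topographies and Morlet time-frequency maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    randomForest,
    rpart,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
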