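Package: ramancell
Title: Chemometric and Neural Classification of Single-Cell Raman Spectra
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discriminates tumor from non-tumor cells using Raman
    micro-spectra of the 600-1800 cm-1 fingerprint region. Provides the
    full analysis chain: a synthetic two-class spectrum simulator
    (pseudo-Voigt bands, fluorescence baseline, cell-level heterogeneity,
    corrupted spectra); preprocessing (axis calibration, substrate
    background subtraction, iterative order-3 polynomial baseline
    correction, vector normalization); PLS-based outlier screening with
    Q-residual and Hotelling T-squared statistics at a 95% confidence
    level; linear discriminant classifiers on raw spectra and on
    principal-component scores, with grid-search tuning, leave-one-out
    component selection and learning curves; a windowed CNN-LSTM ensemble
    with spectral augmentation, a selective (reject-option) branch and
    tree-structured Parzen estimator hyper-parameter search; and blind
    prediction of the tumor fraction of cell mixtures from spectrum-level
    votes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    graphics,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
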