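Package: dnagaksvm
Title: DNA Genetic Algorithm Tuned Tsallis-Entropy Wavelet Features and
    RBF-Kernel SVM for Brain MRI Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary (benign versus malignant) classification of grayscale
    brain MRI slices. Images are decomposed with a decimated multilevel 2D
    Haar wavelet transform, each sub-band is reduced to its Tsallis
    (non-extensive) entropy, and a DNA genetic algorithm over quaternary
    chromosomes jointly tunes the entropy parameter q and the soft-margin
    RBF-kernel SVM hyperparameters (C, sigma) against a stratified
    five-fold cross-validation classification rate. Includes a brain-like
    phantom generator with Rician noise at configurable SNR for fully
    reproducible experiments, broom-style accessors and ggplot2 plots, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    tibble,
    tidyr
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
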