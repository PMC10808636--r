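Package: sozloc
Title: Seizure Onset Zone Localization from rs-fMRI Independent Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated sorting of resting-state fMRI independent components
    (ICs) into measurement noise, resting-state network (RSN), and seizure
    onset zone (SOZ) classes, and localization of the SOZ as the largest
    activation cluster. Combines a convolutional neural network that screens
    noise ICs from rendered spatial-map montages with an expert-knowledge
    model that scores ICs by a learned, sum-to-one linear combination of four
    expert features: activation cluster count and asymmetry, extension of
    activation from gray matter through white matter into the ventricles,
    wavelet-domain sparsity, and sine-dictionary spectral sparsity of the
    BOLD time course. Includes a seeded synthetic IC generator for end-to-end
    evaluation, leave-one-patient-out cross-validation, knowledge-ablation
    experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
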