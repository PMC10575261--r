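Package: diffecg
Title: Conditional Diffusion Synthesis of Multi-Lead ECG Signals
Version: 0.1.0
Authors@R:
    person("diffecg", "maintainers", email = "diffecg@example.org",
           role = c("aut", "cre"))
Description: Generates class-conditional multi-lead electrocardiograms with a
    denoising diffusion probabilistic model whose denoiser is a hybrid
    state-space / local-attention (SPADE-style) network. Includes structured
    state-space (S4) layers with HiPPO initialization, an exact recurrent
    oracle and an O(L log L) convolutional path, Einthoven/Goldberger
    reconstruction of the full 12-lead set from leads I and aVF plus the six
    precordial leads, quality metrics (dynamic time warping, maximum mean
    discrepancy) and classifier-transfer authenticity metrics (multilabel
    accuracy, macro AUROC), a class-conditional synthetic ECG fixture
    generator, a minimal WFDB format-16 reader/writer, and train / sample /
    evaluate command-line workflows. All components run at desk scale on a
    single CPU with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
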