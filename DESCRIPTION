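Package: pcgatoms
Title: Gabor-Atom Decomposition and Set-Based Classification of Phonocardiograms
Version: 0.1.0
Authors@R: person("pcgatoms", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An interpretable pipeline for detecting coronary-artery-occlusion
    acoustic biomarkers in multichannel heart-sound recordings. Four-channel
    phonocardiograms are delay-and-sum beamformed, segmented into full-cycle
    and diastolic windows, and decomposed by matching pursuit over a Gabor
    dictionary with an FFT-accelerated inner-product search. Per-atom features
    (including atomic-influence interaction counts) feed a permutation-invariant
    set classifier that distinguishes pre- from post-intervention sounds; the
    learned per-atom latent space is embedded with UMAP, clustered with DBSCAN,
    and clusters are selectively reconstructed to attribute treatment-related
    spectral-energy changes to specific atom groups. A synthetic
    phonocardiogram generator with planted murmur structure makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    uwot,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
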