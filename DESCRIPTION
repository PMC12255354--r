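Package: clusterecho
Title: Acoustic Detection of Microbubble Cluster Signatures in Ultrasound RF Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the distinctive acoustic signatures of crosslinked
    microbubble clusters (CCMCs) in beamformed ultrasound radio-frequency (RF)
    frame stacks. Provides a labeled synthetic flow-phantom RF simulator,
    the preprocessing chain used in contrast-agent frame selection
    (background subtraction, envelope detection, ROI cropping, thresholding,
    center-element RF extraction), an LSTM autoencoder trained only on
    individual-microbubble echoes whose reconstruction error flags cluster
    echoes as anomalies, and fundamental/subharmonic spectral-band analysis
    of the separated groups, orchestrated end-to-end with full provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
RoxygenNote: 7.3.3
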