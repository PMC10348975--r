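Package: consclust
Title: Soft-Clustering Estimation of Consciousness Levels from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a continuous consciousness-level trace from multichannel
    EEG recordings of patients with disorders of consciousness. Recordings are
    band-pass filtered (0.5-45 Hz, third-order Butterworth) and cut into 3-s
    windows sliding by 1 s; seven features are computed per window (theta and
    beta relative power, normalized 95% spectral edge frequency, Poincare
    ellipsoid radius ratio, Hilbert-binarized Lempel-Ziv complexity,
    theta-band imaginary coherency and theta-tuned weighted symbolic mutual
    information), min-max normalized, and soft-clustered into two clusters by
    both fuzzy c-means and a Gaussian mixture model fitted by EM. The two
    conscious-cluster membership traces are ensemble-averaged into a
    per-window probability of consciousness, which can be evaluated against
    eyes-open/closed scoring via a thresholded accuracy sweep, Spearman
    feature contributions, and inter-cluster centroid distances. A seeded
    synthetic-EEG generator with a known conscious/unconscious state schedule
    supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
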