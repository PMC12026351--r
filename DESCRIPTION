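Package: infomat
Title: Information Matrices for Directed Information Flow in Paired Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the information matrix of a pair of jointly observed
    time series: the m-by-m array of conditional mutual information terms
    I(X_i; Y_j | X^{i-1}, Y^{j-1}) whose subset sums recover mutual
    information, directed information, transfer entropy and instantaneous
    information, together with the exact conservation identities relating
    them.  Entries are estimated under a joint-Gaussian model via
    log-determinants of sample covariance matrices, by plug-in entropy
    estimation for finite-alphabet data, or by conditional gaussianizing
    flows (mixture-of-Gaussian-CDF maps) for nonlinear continuous data.
    Includes simulators for Gaussian autoregressive pairs, nonlinearly
    distorted correlated pairs, and the Ising and Trapdoor finite-state
    channels, plus heatmap visualisation and delimited-text input/output
    for physiological recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
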