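Package: npentropy
Title: Network Permutation Entropy for Nonlinear Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complexity analysis of univariate time series with the network
    permutation entropy (NPE): embedded vectors are symbolized by their
    Bandt-Pompe ordinal patterns and given signed variance weights, a
    connection network links each vector to the first earlier vector sharing
    its pattern within a weight tolerance, and the normalized Shannon entropy
    of the resulting node-score distribution is the complexity statistic.
    Includes the classical permutation entropy (PE), weighted PE (WPE), and
    improved PE (IPE) baselines, deterministic chaotic-signal generators
    (logistic map, simplified Lorenz flow, Caputo fractional-difference Henon
    map), sliding-window complexity profiles, and 1D/2D parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
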