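Package: ebmd
Title: Empirical Blaschke Mode Decomposition for Quasi-Periodic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes uniformly sampled one-dimensional quasi-periodic
    signals (ECG, EEG, machine vibration) into intrinsic mode functions.
    The method combines an adaptive Blaschke transform over a dictionary of
    unit-disk parameters, a-contrario statistical pre-segmentation of the
    resulting Blaschke spectrum into unimodal bands, binary group sparse
    frequency filtering of each mono-component, and fusion of fundamental
    modes that share a periodic-pulse envelope signature.  Includes a
    synthetic signal generator for pulse trains, tonal components and
    baseline drift, plus CSV/WAV input and CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
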