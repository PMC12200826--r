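Package: napinsight
Title: Simulation and Inference for Nap Sleep Stages, Aperiodic EEG
    Activity and Perceptual Insight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse daytime-nap studies of
    insight-like strategy switches. Implements a synthetic cohort
    generator (trial-wise behaviour on a hidden-rule random-dot task,
    multichannel nap EEG with stage-dependent 1/f spectra, and
    hypnograms), sigmoid change-point modelling of abrupt strategy
    switches, FOOOF-style decomposition of power spectra into aperiodic
    and oscillatory components, cluster-based permutation tests over
    channel-by-frequency data, and the nested logistic model comparison
    linking sleep stage and spectral slope to insight.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
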