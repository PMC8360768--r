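Package: lgnchrom
Title: Silent-Substitution Stimulus Design and Cone-Opponency Analysis for
    Mouse LGN Recordings
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying color opponency in the mouse lateral
    geniculate nucleus with photoreceptor-isolating stimuli. Provides
    Govardovskii A1 opsin nomograms and opsin-effective photon-flux
    arithmetic, a multiprimary silent-substitution solver with gamut and
    residual-contrast validation, generators for square-wave, step and
    white-noise stimulus waveforms, a linear-nonlinear-Poisson simulator
    producing trial-structured spike trains from ground-truth model
    neurons, shuffle-null response detection with cycle histograms,
    cone-opponency and melanopsin-response classification, spike-triggered
    averaging, receptive-field mapping from sparse bar/square stimuli, a
    random-wiring center-surround retinal model over the dorsoventral cone
    opsin gradient, and an end-to-end pipeline with anatomical property
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
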