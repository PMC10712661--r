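Package: emophys
Title: Multimodal Physiological Feature Extraction for Emotion Elicitation Studies
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing emotion-elicitation experiments
    driven by standardized affective picture and sound libraries. Provides a
    three-phase protocol scheduler, synthetic multimodal recordings (ECG, blood
    volume pulse, galvanic skin response, EEG, pupillometry) with known ground
    truth, per-signal preprocessing and feature extraction chains (electrodermal
    phasic decomposition and SCR peak detection, point-process inverse-Gaussian
    heartbeat modelling with time-varying autoregressive spectral HRV indices,
    pulse arrival time and volume pulse from ECG-anchored fiducials, EEG band
    powers with a beta/theta attention index, pupil diameter cleaning and
    spectral features), and the cross-phase nonparametric comparison stage
    (Shapiro-Wilk, Friedman, Tukey-type post-hoc).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
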