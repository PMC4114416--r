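Package: coughSpot
Title: Keyword-Spotting Detection of Cough Events in Ambulatory Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implementation of an automated ambulatory
    asthma-symptom monitor. Continuous single-channel audio is framed,
    converted to mel-cepstral feature vectors, and decoded segment-by-segment
    (6 s blocks) with a token-passing Viterbi decoder over a loop grammar of
    hidden Markov models (one cough keyword model plus filler models for
    background noise), yielding timestamped cough events, audit retention of
    positive and randomly sampled segments, and hourly symptom counts.
    Companion modules score accelerometer-derived activity on the device's
    0-24 scale, keep a medication diary, assemble daily reports, and compute
    the validation statistics (event matching, sensitivity, false positives
    per hour, rater agreement) and acceptance-survey statistics (scale
    scoring with cutoff, item agreement, Cronbach's alpha, item
    correlations). A seeded synthetic module generates every input the
    pipeline consumes: parametric cough bursts in background noise at
    controlled SNR, cough-free distractor audio, coupled activity traces,
    and survey response tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
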