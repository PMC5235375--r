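Package: quero
Title: Acoustic Detection and Vocal-Activity Phenology for the Southern Lapwing
Version: 0.1.0
Authors@R:
    person("Pantanal Acoustics", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: A GMM-UBM (Gaussian mixture model - universal background model)
    detector for the multi-harmonic calls of the Southern Lapwing (Vanellus
    chilensis) in continuous soundscape recordings, together with the
    statistics needed to validate it and to turn its detections into
    phenology: a linear-frequency cepstral coefficient (LFCC) front end,
    per-frame log-likelihood-ratio scoring, temporal smoothing of frame
    decisions into timestamped call events, precision/accuracy/correct/missed
    validation metrics with double-hit and unconfirmed-event handling,
    false-positive-corrected day/night activity tables, diel profiles,
    water-level and lunar-phase activity tests, and a synthetic soundscape
    and breeding-season simulator so the whole pipeline is testable without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
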