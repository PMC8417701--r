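Package: mwbench
Title: Mental Workload Estimation from Multimodal Physiology with
    Time-Aware Validation Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate binary mental workload (low vs. high) from
    multimodal physiological recordings: EEG spectral band powers and the
    engagement index, cardiac features (heart rate and SDNN heart-rate
    variability from RR intervals with Malik-rule artifact cleaning),
    eye-tracking fixation, blink, area-of-interest and pupil features, and
    behavioral task scores including a Gaussian heading-compliance score.
    Provides a synthetic multimodal session generator with configurable
    workload effects and slow signal non-stationarity, and a classifier
    benchmark comparing traditional (time-agnostic) cross-validation with an
    ecological design in which training data strictly precede testing data,
    for both intra- and inter-participant scopes, against a binomial adjusted
    chance level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    MASS,
    rpart,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
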