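Package: mcsv
Title: Multichannel Epileptic Seizure Classification with Critical Spectral Verge Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Channel-wise classification and localization of epileptic seizure
    activity in multichannel scalp EEG. Recordings are cleaned by
    multiresolution adaptive filtering (wavelet soft-threshold denoising
    followed by per-band normalized-LMS adaptive filtering), summarized per
    segment and frequency band by the critical spectral verge (CSV) -- the
    highest frequency whose power spectral density exceeds the band's average
    spectral power, refined by a flower pollination algorithm with Levy
    flights -- and classified segment-by-segment with SVM, k-NN or K-Means.
    Includes EDF input/output, a synthetic EEG generator with ground-truth
    seizure annotations, cross-validated evaluation (sensitivity, specificity,
    accuracy, average detection rate) and per-channel seizure localization
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    class,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
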