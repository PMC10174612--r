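Package: neuroglyc
Title: Coupling and Decoding of Intracranial Neural Activity and
    Interstitial Glucose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking multichannel intracranial powerband activity
    to continuous interstitial glucose: preprocessing of stereo-EEG into
    smoothed Hilbert powerband envelopes, alignment with 5-minute continuous
    glucose monitor series, lag-resolved cross-correlation with block
    permutation nulls, Morlet wavelet coherence with circadian phase lag and
    circadian/ultradian decomposition, stimulation-evoked potential (CCEP)
    summaries, and a sparse (LASSO) spectro-spatial glucose decoder with
    circadian controls and bootstrap channel importance.  A synthetic-data
    generator with fully known circadian/ultradian structure, coupling lags
    and noise provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
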