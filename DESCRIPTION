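Package: hfqrs
Title: High-Frequency Content Analysis of QRS Complexes by Continuous
    Wavelet Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of the high-frequency (85-130 Hz)
    spectral content of QRS complexes in multi-lead surface ECG records, a
    candidate risk marker for sudden cardiac death. Implements a modified
    Pan-Tompkins beat detector (differentiation, squaring, 99.5th-percentile
    typification, fixed 0.6 threshold, V6 R-peak alignment, 145 ms window
    extraction), a Morlet continuous wavelet transform restricted to the
    85-130 Hz band, cumulative-power and intensity summary metrics, and
    two-group cohort comparison. A synthetic 12-lead ECG generator with
    controllable intra-QRS high-frequency bursts makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'detection.R'
    'ecg-io.R'
    'hfqrs-package.R'
    'pipeline.R'
    'plot.R'
    'quantify.R'
    'synthetic.R'
    'utils.R'
    'wavelet.R'
    'wfdb.R'
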