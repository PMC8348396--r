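Package: afwaterfall
Title: Waterfall Hybrid Classification and Prediction of Atrial
    Fibrillation from Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for atrial-fibrillation (AF) screening on single-lead
    electrocardiograms: a synthetic ECG generator with ground-truth beat
    annotations (normal sinus rhythm, AF with fibrillatory waves, and the
    sinus rhythm preceding paroxysmal AF), a Pan-Tompkins style QRS
    detector with adaptive dynamic thresholds and search-back, P-wave
    delineation, a 14-feature time/frequency scheme built on RR-interval
    statistics, PR interval, P amplitude and level-4 bior5.5 wavelet
    coefficients, radial-basis-function support vector machine
    classifiers tuned either by grid search or by an improved
    quantum-behaved particle swarm optimizer, a two-stage waterfall
    ensemble that first diagnoses AF and then predicts paroxysmal AF
    among the remaining segments, one-vs-rest evaluation metrics, and a
    digitizer that recovers a calibrated millivolt signal from rasterized
    clinical ECG report images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    e1071,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
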