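Package: rhythmResample
Title: Replicate Resampling and Consensus Calling for Rhythmic Transcript
    Detection in Time-Course Expression Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies rhythmically expressed genes in time-course
    expression experiments where each time point is sampled destructively
    from different individuals. Builds single-replicate datasets by
    randomly resampling among biological replicates at every time point,
    runs a rhythmicity detector (an ARSER-style autoregressive spectral /
    harmonic regression pipeline, a HAYSTACK-style pattern-correlation
    classifier, or an FFT-initialised cosine least-squares fitter) on each
    resampled dataset, and calls a gene rhythmic when it is detected in at
    least k of the resampled datasets. Includes simulators for entrained
    (LD), free-running (LL) and limit-cycle-oscillator based circadian
    time courses with ground-truth labels, and benchmarking utilities that
    score true and false positives against the truth across consensus
    thresholds, replicate counts and resample counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    minpack.lm,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, TimeCourse, Transcriptomics, StatisticalMethod,
    Regression
RoxygenNote: 7.3.3
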