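Package: glycofp
Title: Two-Phase Decomposition of Neural Photometry Responses to Oral Glucose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking fiber-photometry recordings of
    hypothalamic AgRP neuron activity to continuously monitored arterial
    glucose after an oral glucose load. Provides signal cleaning for both
    modalities (robust despiking, median filtering, causal smoothing,
    zero-phase low-pass, baseline z-scoring), glucose excursion metrics
    (onset detection with sustain criterion, peak and derivative metrics,
    half-max recovery, positive-only incremental area under the curve),
    spectral band-power onset testing against jittered pseudo-event nulls,
    an early-response template regression model with cross-validated lag
    selection and residual (second-phase) extraction, lagged Spearman
    cross-correlation with pseudosession nulls, and cohort-level statistics
    with subject fixed effects and robust standard errors. A seeded
    synthetic-cohort generator reproduces the statistical structure the
    pipeline assumes so that every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    sandwich,
    lmtest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
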