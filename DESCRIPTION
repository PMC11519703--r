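Package: gazepipe
Title: Lab and Webcam Visual-World Eye-Tracking Analysis Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing in-lab and webcam-based visual-world eye-tracking
    studies of sentence-picture matching. Provides a synthetic-study generator with
    dual-modality gaze streams (high-rate lab sampling versus sparse, jittery,
    temporally lagged webcam sampling), viewport-proportional area-of-interest
    geometry and gaze-sample labeling, two-standard-deviation timestamp and
    reaction-time trimming, 100-ms binning into target-gaze proportions, mixed-effects
    accuracy and reaction-time models, weighted quasibinomial per-bin proportion
    models with Pearson-dispersion standard errors and a bin-wise contrast engine,
    and a control-minus-aphasia difference-series (delta-gaze) analysis with
    peak, dip, and cross-correlation estimators of the web-versus-lab temporal lag.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
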