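Package: MCTrials
Title: Design and Analysis of Mouse Clinical Trials
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical toolkit for mouse clinical trials (MCTs), in which a
    panel of mouse tumor models (PDX, CDX or syngeneic), each with one or more
    mice per arm, is used to evaluate drug efficacy. Implements categorical
    response classification (RECIST-based, 3-category, mRECIST, 5-category)
    and continuous efficacy endpoints (tumor volume doubling time, RTV ratio,
    tumor growth inhibition, growth-rate ratio, AUC ratio) on exponential
    tumor-growth kinetics; subsampling procedures relating mouse numbers to
    measurement accuracy; three-level linear mixed models for MCTs viewed as
    clustered longitudinal studies, including single-gene biomarker scanning;
    an additive frailty survival model with Weibull baseline hazard and
    bivariate normal model-level frailties; simulation-based power analysis
    for balanced n:n designs; and a synthetic-MCT generator with known ground
    truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
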