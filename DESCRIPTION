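Package: pupilsub
Title: Silent-Substitution Pupillometry and Melanopsin-Directed Pupil
    Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing photoreceptor-isolating (silent
    substitution) light stimuli on multi-primary light sources, computing
    alpha-opic radiances and Weber contrasts from spectral radiance data,
    preprocessing raw pupillometry recordings (artifact masking, gap
    interpolation, Butterworth smoothing, baseline normalization),
    extracting pupil-response metrics including the post-illumination
    pupil response (PIPR), and running two-group diagnostic statistics
    (Welch and paired t-tests, Spearman correlation, ROC/AUC with DeLong
    confidence intervals, binormal sensitivity/specificity analytics).
    Includes a synthetic cohort generator that emulates the trial
    protocol, blink artifacts, and configurable group effect sizes so the
    whole pipeline is testable without access to raw recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pROC,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
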