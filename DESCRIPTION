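Package: rvcpf
Title: Simplified Right Ventricular Volumetry with the Cone-Pyramid Formula
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simplified right ventricular (RV) quantification from
    two linear four-chamber measurements using the truncated cone minus
    rhomboid pyramid formula (CPF, V = 1.21 * D^2 * L), together with the
    disk-summation short-axis volumetry it is usually compared against.
    Includes an explicit geometric phantom family whose closed-form volume
    coefficient can be calibrated to the CPF constant, a synthetic cohort
    generator (paired end-diastolic/end-systolic phantoms, rasterized
    short-axis mask stacks, noisy observer measurements, an outflow-tract
    volume fraction invisible to four-chamber measurements), and the full
    method-comparison statistical stage: Pearson correlation, Bland-Altman
    agreement, ROC curves with Youden-index cut-offs, and two-way random
    absolute-agreement intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
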