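Package: bse
Title: Body Size Estimation Psychophysics and M/EEG Source Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing body size estimation (BSE) experiments of the
    kind used to study body image disturbance in anorexia nervosa. Fits Weibull
    psychometric functions to dichotomous ("narrower"/"wider") size judgments
    of body pictures spanning six BMI categories, derives fitted BMIs and body
    perception indices (BPI), and runs the behavioural group statistics
    including a median-split subgrouping. For parallel MEG/EEG recordings the
    package provides a preprocessing chain (zero-phase Butterworth filtering,
    resampling, epoching, baseline correction, artifact screening, condition
    averaging), an L2 minimum-norm source estimate on a spherical shell of
    evenly distributed dipoles with Tikhonov regularisation and analytic
    spherical-conductor forward models, and mass-univariate mixed-design
    repeated-measures ANOVA with nonparametric spatiotemporal
    cluster-permutation control, polynomial trend contrasts and post-hoc
    tests. A synthetic-data generator emulates the full experimental design
    (66 stimuli, 198 trials per task, constrained pseudo-random sequences,
    Weibull observers, dipole-source sensor recordings) so the whole pipeline
    is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
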