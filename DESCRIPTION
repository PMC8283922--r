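Package: handassess
Title: Clinimetric Analysis of Robot-Assisted Hand Sensorimotor Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a battery of five robot-assisted assessments of
    hand function at the index finger metacarpophalangeal joint: gauge position
    matching (proprioception), fast target reaching, active/passive range of
    motion and maximum fingertip force (motor function), and trajectory
    following (sensorimotor function). Provides task stimulus generation and
    signal conditioning, extraction of the primary outcome measure of each
    task from trial-level data, test-retest reliability statistics (ICC(A,k)
    with F-based confidence intervals, standard error of measurement, smallest
    real difference, systematic shift, Bland-Altman limits of agreement),
    discriminant and concurrent validity statistics (Kruskal-Wallis with
    Bonferroni-corrected pairwise follow-ups, ROC AUC, Spearman correlations
    with clinical scales, partial Spearman independence analysis), normative
    modelling with linear mixed-effects confound removal and z-score
    impairment classification, and a synthetic patient-cohort simulator that
    reproduces the statistical structure such studies assume, so the whole
    pipeline can be exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
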