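Package: wminterference
Title: Simulation and Analysis of Interference in Continuous-Report Working Memory
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing continuous-report (delayed
    estimation) visual working-memory experiments in which a distracting or
    interrupting stimulus appears during the retention delay at a temporally
    predictable or unpredictable moment. Provides a synthetic-cohort generator
    reproducing the factorial block design (interference type x temporal
    predictability x interference onset), trial- and participant-level
    exclusion rules, reproduction-error metrics with within-subject standard
    errors, a maximum-likelihood three-component von Mises mixture model
    (target / non-target swap / uniform guess) on the doubled orientation
    circle, a moving-window response-bias curve with signed area-under-curve
    integration and equated per-condition bias, fully within-subjects
    repeated-measures ANOVA with generalized eta squared, paired t tests with
    Cohen's d and Bonferroni correction, and exact noncentral-t power analysis
    for paired designs. A small command-line pipeline orchestrates
    simulate / analyze / recover runs with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
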