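Package: corrsubpop
Title: Correlation-Guided Subpopulation Discovery in Biochemical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies subpopulations of subjects whose paired biochemical
    measurements correlate above a target threshold, using two greedy
    procedures: agglomerative growth from a robustly seeded linear axis by
    minimising a correlation-loss measure, and divisive pruning of the whole
    cohort by maximising a correlation-gain measure. Includes Pearson
    correlation tables with significance screening, enzyme-activity
    normalisation (citrate synthase and coenzyme Q10 ratios), a trimmed
    k-lines initializer for detecting linear clusters in scatter, agreement
    scoring between the two search procedures, and a synthetic cohort
    generator with planted ground truth for validation. Motivated by the
    assessment of muscle coenzyme Q10 content and citrate synthase activity
    as biomarkers of mitochondrial respiratory-chain enzyme activities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'biomarker-table.R'
    'tabular-io.R'
    'preprocessing.R'
    'correlation.R'
    'cluster-init.R'
    'search.R'
    'agreement.R'
    'synthetic.R'
    'reference-cohort.R'
    'plotting.R'
    'workflow.R'
    'corrsubpop-package.R'
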