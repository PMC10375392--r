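Package: qcscreen
Title: Qualifying Comorbidity Set Screening and Feasibility-Trial Evaluation
Version: 0.1.0
Authors@R:
    person("qcscreen", "developers", email = "qcscreen@example.org",
           role = c("aut", "cre"))
Description: A desk-scale rule engine for identifying multimorbid patients by
    the presence of a Qualifying Comorbidity Set (QCS): a versioned JSON
    catalog of comorbid conditions, their ICD-9/10-CM, CPT and HCPCS code
    lists, and qualifying sets of one to three conditions; a claims-code to
    condition mapper; batch and incremental (early-terminating) subset
    matchers; an emulation of the paged screening flow used in mobile
    screening apps; and the statistics used to evaluate a screening
    feasibility trial (trial-level sensitivity and specificity, selection
    error tallies, paired timing comparisons and 5-point Likert survey
    summaries).  Includes a synthetic, non-clinical toy catalog, the five
    published trial scenarios at printed resolution, and seeded generators
    for synthetic patients and rater trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
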