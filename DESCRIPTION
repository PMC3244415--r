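Package: vulnmeta
Title: Meta-Analysis and Meta-Regression of Genetic Vulnerability to LDL
    Cholesterol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Study-level tools for detecting and quantifying genetic
    effect modification of the LDL cholesterol--cardiovascular risk
    relationship ("vulnerability" to LDL). Builds unadjusted relative
    risks and odds ratios from 2x2 tables, pools them with
    DerSimonian-Laird inverse-variance random-effects meta-analysis,
    fits random-effects meta-regression of study log-effects on mean
    LDL (REML or method of moments), standardizes randomized-trial
    effects per mmol/L of LDL reduction, and compares the treatment
    benefit predicted from the meta-regression slope with the benefit
    observed in genotype-stratified trials. A synthetic-data module
    simulates cohorts, case-control studies, and stratified trials
    under a log-linear genotype-by-LDL interaction risk model so the
    whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
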