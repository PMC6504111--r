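Package: odorminer
Title: Subgroup Discovery of Descriptive Structure-Odor Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines descriptive structure-odor rules from tables of molecular
    descriptors annotated with multi-label olfactory qualities. Rules are
    conjunctions of closed numeric intervals (interval patterns) discovered by
    beam search and scored with a support-adaptive F-beta measure that favours
    precision for rare qualities and recall for frequent ones. Per quality, the
    best rule or combination of up to twelve rules is selected by Euclidean
    distance to the ideal (error 0, recall 1) point, its F-measure is tested
    against a bootstrap confidence interval of random same-size molecule
    samples, and selected rulesets can be validated on independently rated
    odorant panels with one-way ANOVA and eta-squared effect sizes. Includes a
    synthetic-data generator with planted interval-box rules and unbalanced
    multi-label annotations for end-to-end benchmarking, plus a command-line
    pipeline (simulate, mine, select, bootstrap, validate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
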