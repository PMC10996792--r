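Package: rxnet
Title: Shared-Patient Prescriber Networks and Homophily in Risky Prescribing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying homophily in risky prescribing on shared-patient
    physician networks built from prescription-claims data. Includes a synthetic
    claims generator (refill chains, multi-class concurrent exposure, planted
    deprescribing events, assortative patient-sharing), construction of the
    mutual binarized shared-patient network and its largest connected component,
    refill merging and 8-state prescription trajectory modeling over opioids,
    benzodiazepines and sedative-hypnotics, heuristic attribution of
    deprescribing events to physicians, per-physician transition-responsibility
    matrices and prescribing indexes, exact maximum-likelihood fitting of
    dyad-independent exponential random graph models with identifiability
    diagnostics, and attribute-restricted triadic homophily statistics with
    permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
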