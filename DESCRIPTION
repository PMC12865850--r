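Package: toxtrend
Title: Trend Analysis of Drug-Combination Synergy and Toxicity Metrics
    Against Ordinal Interaction Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate whether cancer drug-combination synergy
    scores (Bliss, HSA, Loewe, ZIP, S variants) and common toxicity-penalty
    metrics (drug target and pathway Jaccard overlap, Morgan-fingerprint
    Tanimoto similarity, protein-interaction-network target distance and
    two-hop neighborhood overlap) track ordinal clinical drug-drug
    interaction severity (Minor, Moderate, Major). Provides readers for
    DrugComb-, DrugBank-, DDInter-, Reactome- and STRING-style tables, a
    nonparametric trend-testing battery (D'Agostino-Pearson normality
    screen, tie-corrected Kruskal-Wallis with rank eta-squared, Dunn
    post-hoc with Bonferroni correction and Cliff's delta,
    Jonckheere-Terpstra ordered trend test with tie-corrected normal
    approximation and permutation mode), correlation summaries, a synthetic
    data generator with plantable monotone couplings, and an orchestration
    layer that emits tidy result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
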