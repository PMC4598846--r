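Package: racs
Title: Ranking-System Prediction of Synergistic Anticancer Drug Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage ranking of candidate anticancer drug pairs for
    synergy. A preliminary stage scores every unlabelled pair by
    semi-supervised manifold ranking against known synergistic ("bait")
    pairs in a seven-dimensional space of protein-protein-interaction
    network and annotation features (GO-based mutual information, mean
    target distance, drug-combination interference, three
    centrality-weighted efficacy scores, unrelated-pathway fraction).
    An ensemble of ranking runs over bait subsamples is condensed by
    top-fraction consistency and exact Spearman-footrule consensus, and
    a secondary stage filters the consensus list with permutation tests
    on differentially-expressed-gene overlap and cancer-pathway
    coverage. Includes Chou-Talalay median-effect fitting and
    combination-index synergy calls, ranking evaluation metrics
    (probabilistic concordance index, ROC AUC, true-positive rate,
    Fisher's exact pick-up-rate test), and seeded synthetic-data
    generators that emulate every input with plantable synergy signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
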