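Package: crystalprop
Title: Sequence-Based Prediction of Protein Production, Purification and
    Crystallization Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Alignment-free prediction of the outcome of protein
    crystallization pipelines from amino-acid sequence alone. Converts a
    protein chain into 1276 numeric descriptors (amino-acid and dipeptide
    composition, grouped composition/transition/distribution statistics over
    seven physicochemical residue alphabets, windowed residue-index profiles,
    whole-chain physicochemical indices, and summaries of predicted intrinsic
    disorder and sequence complexity), selects a compact per-outcome feature
    subset by biserial-correlation filtering, redundancy pruning and greedy
    wrapper search maximizing cross-validated AUC, and fits one logistic
    regression model per pipeline outcome: failure of material production
    (MF), failure to purify (PF), failure to crystallize (CF), and success of
    diffraction-quality crystallization (CR). Includes percentile-based
    prediction confidence tiers, bootstrap evaluation with MCC, accuracy and
    AUC, trial-status annotation utilities, and a synthetic-data generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    nortest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
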