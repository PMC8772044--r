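Package: mcsdti
Title: Drug-Target Interaction Prediction with Multiple Classification
    Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTI) from a binary
    interaction matrix plus drug fingerprints and protein descriptors by
    splitting protein targets into two parts according to their number of
    known interactions. Targets with larger numbers of interactions (TWLNI)
    are predicted by a per-target CART decision tree trained only on that
    target's own labelled drugs; targets with smaller numbers of
    interactions (TWSNI) are predicted by nearest-profile similarity
    transfer over drug and target similarity matrices. The two parts are
    evaluated independently (macro-averaged and pooled AUC respectively)
    under drug-wise fivefold cross-validation, so that improvements on
    sparsely annotated targets are not overwhelmed by heavily annotated
    ones. Includes a synthetic chemogenomic data generator with skewed
    target degrees and a plantable fingerprint signal, the classical
    comparison methods (global decision tree, weighted profile,
    network-based inference), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    rpart,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
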