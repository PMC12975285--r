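Package: binpu
Title: Positive-Unlabeled Learning for Compound-Protein Interaction
    Prediction with Bin Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts compound-protein interactions (CPI) when only positive
    interaction labels are available. Implements a positive-unlabeled (PU)
    learning strategy that generates an unlabeled set by pairwise combination
    of the observed compounds and proteins, hides a fraction of the known
    positives as spies, partitions the unlabeled pool into random bins, trains
    one classifier per bin with the unlabeled members treated as negatives,
    and averages the per-bin posterior probabilities into an ensemble score.
    Confident scores become pseudo positive and pseudo negative labels; the
    spies-capture-rate diagnostic reports how many hidden positives the
    ensemble recovers. A final classifier is trained on the truly positive
    and pseudo-labeled pairs under a composite objective: binary cross-entropy
    plus a weighted penalty on prediction error over the truly positive
    slice. Ships a hashed k-mer/n-gram featurizer with a single-hidden-layer
    reference backbone (any classifier satisfying the fit/predict-probability
    contract can be plugged in), F1-based threshold and lambda selection, a
    positive-upweighting baseline, and a synthetic-world generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
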