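Package: metapara
Title: Meta-Weighted Domain-Adaptive Paraphrase Augmentation for Text Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-reweighting-based multi-level optimization for domain-adaptive
    paraphrase augmentation in low-resource text classification. A meta-weight
    network maps each paraphrase training pair's teacher-forcing loss to a data
    weight in (0,1); the weights are learned by back-propagating the validation
    loss of a downstream classifier through one-step unrolls of the paraphraser
    and classifier, using a finite-difference hypergradient. Ships tiny reference
    models (seq2seq paraphraser, bidirectional-LSTM classifier) with hand-derived
    gradients, an exact hypergradient oracle for verification, a synthetic
    two-domain corpus generator, evaluation metrics (macro and one-vs-one AUC
    protocols), and a command-line interface.
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
    yaml,
    withr
Config/testthat/edition: 3
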