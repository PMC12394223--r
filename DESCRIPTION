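Package: knowens
Title: Knowledge-Ensemble Uncertainty Scoring for Open-Set Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-hoc uncertainty scoring toolkit for open-set recognition,
    aimed at plant-disease image classifiers that must reject samples from
    disease classes absent at training time. Implements the classic
    post-hoc scores (maximum softmax probability / max-logit, energy,
    maximum concept matching), cosine-similarity feature-bank
    dissimilarity scores against fine-tuned ("domain-specific knowledge")
    and frozen pre-trained ("general knowledge") embedding spaces, min-max
    normalized score-level ensemble fusion, and a threshold decision rule.
    Ships the standard open-set evaluation protocol (FPR at 95% TPR,
    AUROC with the known-positive convention, closed-set accuracy),
    few-shot training-bank subsampling with disjoint known/unknown split
    validation, a seeded synthetic open-set embedding generator for fully
    offline testing, and TSV/JSON file formats with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
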