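Package: compsym
Title: Composition-Driven Symptom Phrase Recognition from Consultation Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation-free recognition of symptom phrases in free-text
    medical consultation records. Phrase composition is learned from a
    dictionary of standard symptom phrases alone: every dictionary phrase is
    automatically annotated with BIES (Begin/Intermediate/End/Single)
    position labels, per-component position probabilities are estimated as
    multinomial maximum-likelihood frequencies, and pairwise semantic
    compatibility between components is scored through the Jensen-Shannon
    divergence between embedding-neighborhood cluster distributions. The two
    models are combined to segment unseen sentences, filter dispensable
    intermediate words, and emit symptom phrases never observed verbatim in
    the dictionary. Includes IoU-thresholded micro/macro precision, recall
    and F1 evaluation, dictionary-lookup and bidirectional maximal-matching
    baselines, and a synthetic benchmark generator with known compositional
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
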