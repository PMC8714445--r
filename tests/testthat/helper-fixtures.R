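# Small in-code fixtures shared across test files.

# a tokenized sentence without going through preprocess()
make_sentence <- function(tokens, kept = rep(TRUE, length(tokens)),
                          record_id = "t1") {
  structure(list(record_id = record_id, sentence = 1L, tokens = tokens,
                 kept = kept),
            class = "tokenized_sentence")
}

phrase_list <- function(..., granularity = "word") {
  lapply(list(...), function(cc) {
    symptom_phrase(paste(cc, collapse = " "), cc, granularity)
  })
}

stats_from <- function(...) {
  position_stats(annotate_dictionary(phrase_list(...)))
}

# interaction model from hand-made neighbourhood rows
manual_model <- function(rows, nu = 7.5, gamma = 0) {
  nb <- do.call(rbind, rows)
  rownames(nb) <- names(rows)
  interaction_model(nb, interaction_params(nu = nu, gamma = gamma))
}

# dictionary with mixed positional behaviour used by several recognizer tests:
# b* mostly begin, e* mostly end, m* interior, s singleton that also occurs
# as an interior
mixed_dictionary <- function() {
  phrase_list(
    c("b1", "m1", "e1"), c("b1", "e1"), c("b1", "m2", "e2"),
    c("b2", "m1", "m2", "e1"), c("b2", "e2"), c("b1", "s1", "e2"),
    c("s1"), c("s1"), c("s2"), c("b2", "m1", "e2")
  )
}
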