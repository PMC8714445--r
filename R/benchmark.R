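#' Run the full pipeline on a synthetic benchmark
#'
#' Convenience driver that generates a dictionary and corpus from a
#' [generator_config()], trains the position and interaction models,
#' extracts phrases in one or more modes, and evaluates them against the
#' gold annotations at one or more IoU thresholds. This is the desk-scale
#' surrogate for the full consultation-corpus experiments; embeddings are
#' trained on the dictionary plus the (unlabeled) corpus sentences so that
#' filler words obtain their own embedding context.
#'
#' @param config A [generator_config()].
#' @param modes Extraction modes to run (see [extract_config()]).
#' @param delta Utility / interaction threshold.
#' @param epsilon Numeric vector of IoU thresholds.
#' @param dim,window,epochs,negative Embedding hyper-parameters (desk-scale
#'   defaults; the full-scale method uses `dim = 500`).
#' @param params An [interaction_params()]; its seed defaults to the
#'   generator seed.
#' @param supplementary Train embeddings on dictionary + corpus (`TRUE`,
#'   default) or dictionary only.
#' @return List with `reports` (`reports[[mode]][[as.character(eps)]]` is an
#'   [evaluate_extractions()] report), `extractions` (per mode), `stats`,
#'   `space`, `model`, `dict`, `corpus`.
#' @export
run_benchmark <- function(config = generator_config(),
                          modes = c("full", "no-interaction", "no-position"),
                          delta = 0.2, epsilon = 0.6,
                          dim = 48L, window = 5L, epochs = 10L,
                          negative = 5L, params = NULL,
                          supplementary = TRUE) {
  dict <- generate_dictionary(config)
  corpus <- generate_corpus(dict)
  stats <- position_stats(annotate_dictionary(dict$phrases))
  corpus_tokens <- lapply(strsplit(unname(corpus$texts), " ", fixed = TRUE),
                          function(x) x[nzchar(x)])
  space <- train_embeddings(dict$phrases, dim = dim, window = window,
                            epochs = epochs, negative = negative,
                            corpus = if (supplementary) corpus_tokens,
                            seed = config$seed)
  if (is.null(params)) params <- interaction_params(seed = config$seed)
  model <- fit_interaction(space, params)
  sentences <- preprocess(
    corpus$texts,
    filters = filter_config(vocab = union(rownames(stats),
                                          space$vocabulary),
                            rare_min = 0L))
  reports <- list()
  extractions <- list()
  for (mode in modes) {
    ext <- extract_corpus(sentences, stats, model,
                          extract_config(mode = mode, delta = delta))
    extractions[[mode]] <- ext
    reports[[mode]] <- list()
    for (eps in epsilon) {
      reports[[mode]][[as.character(eps)]] <-
        suppressWarnings(evaluate_extractions(ext, corpus$gold, eps))
    }
  }
  list(reports = reports, extractions = extractions, stats = stats,
       space = space, model = model, dict = dict, corpus = corpus)
}
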