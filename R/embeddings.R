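#' Component embedding space
#'
#' Wraps a numeric matrix of per-component embedding vectors (one row per
#' vocabulary member, row names are the components). Constructed either
#' directly from a matrix (useful in tests and for externally trained
#' vectors) or by [train_embeddings()].
#'
#' @param vectors Numeric matrix with unique, non-empty row names and finite
#'   values.
#' @return Object of class `embedding_space` with fields `vectors`, `dim`,
#'   `vocabulary`.
#' @export
embedding_space <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  vocab <- rownames(vectors)
  if (is.null(vocab) || anyDuplicated(vocab) || !all(nzchar(vocab))) {
    stop("embedding matrix needs unique non-empty row names")
  }
  if (!all(is.finite(vectors))) stop("embedding vectors must be finite")
  structure(list(vectors = vectors, dim = ncol(vectors), vocabulary = vocab),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> %d components, dimension %d\n",
              length(x$vocabulary), x$dim))
  invisible(x)
}

#' Train skip-gram component embeddings
#'
#' Trains skip-gram embeddings with negative sampling on the component
#' sequences of the dictionary phrases (each phrase is one training
#' sentence), optionally supplemented with tokenized corpus sentences.
#' Training is single-threaded and fully reproducible under a fixed seed.
#'
#' @param phrases List of [symptom_phrase()] objects.
#' @param dim Embedding dimension (the full-scale default of the method is
#'   500; desk-scale analyses use much smaller values).
#' @param window Maximum context window (dynamically shrunk per position, as
#'   in classical skip-gram training).
#' @param epochs Training epochs.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate (linear decay).
#' @param min_count Minimum total corpus frequency for a component to be
#'   retained. Defaults to 1 so that every dictionary component receives a
#'   vector (out-of-vocabulary status is reserved for words absent from the
#'   dictionary).
#' @param corpus Optional supplementary corpus: list of character vectors of
#'   tokens (e.g. tokenized consultation sentences). Default off.
#' @param seed Integer seed.
#' @return An [embedding_space()].
#' @export
train_embeddings <- function(phrases, dim = 100L, window = 5L, epochs = 10L,
                             negative = 5L, alpha = 0.05, min_count = 1L,
                             corpus = NULL, seed = 1L) {
  stopifnot(length(phrases) > 0L)
  sentences <- lapply(phrases, function(p) p$components)
  if (!is.null(corpus)) sentences <- c(sentences, corpus)
  tokens <- unlist(sentences, use.names = FALSE)
  freq <- table(tokens)
  vocab <- names(freq)[freq >= min_count]
  if (length(vocab) == 0L) {
    stop_config("embedding vocabulary is empty after min-count filtering")
  }
  vocab <- vocab[order(match(vocab, tokens))]  # first-occurrence order
  idx <- seq_along(vocab) - 1L
  names(idx) <- vocab
  enc <- lapply(sentences, function(s) {
    unname(idx[s[s %in% vocab]])
  })
  enc <- enc[vapply(enc, length, 1L) > 0L]
  mat <- sgns_train_cpp(enc, length(vocab),
                        as.numeric(freq[vocab]), as.integer(dim),
                        as.integer(window), as.integer(epochs),
                        as.integer(negative), alpha, as.integer(seed))
  rownames(mat) <- vocab
  embedding_space(mat)
}

#' Read/write embeddings in word2vec text format
#'
#' First line `<vocab> <dim>`, then one `token v1 ... vd` line per
#' component.
#'
#' @param space An [embedding_space()].
#' @param path File path.
#' @return `read_embeddings()` returns an [embedding_space()].
#' @export
write_embeddings <- function(space, path) {
  stopifnot(inherits(space, "embedding_space"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(space$vocabulary), space$dim), con)
  apply_rows <- vapply(seq_along(space$vocabulary), function(i) {
    paste(c(space$vocabulary[i],
            format(space$vectors[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)), collapse = " ")
  }, character(1))
  writeLines(apply_rows, con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(mat) <- vocab
  embedding_space(mat)
}

# row-normalized cosine similarity matrix of an embedding space
cosine_matrix <- function(vectors) {
  nrm <- sqrt(rowSums(vectors^2))
  nrm[nrm == 0] <- 1
  v <- vectors / nrm
  tcrossprod(v)
}
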