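#' Corpus preprocessing
#'
#' Splits each consultation record into sentences on a configurable
#' terminator set, tokenizes every sentence, and marks non-informative
#' tokens: extremely common tokens, rare tokens, and tokens unknown to both
#' the position model and the embedding vocabulary. Marked tokens are not
#' removed — they keep their position (so spans remain contiguous) but carry
#' `kept = FALSE` and can only act as skippable or filler material during
#' recognition.
#'
#' @param texts Character vector of consultation records (one record per
#'   element).
#' @param tokenizer Tokenizer function (see [tokenizers]).
#' @param filters A [filter_config()], or `NULL` to keep every token.
#' @param terminators Regex character class of sentence terminators.
#' @param record_ids Optional record identifiers (default: names of `texts`
#'   or `r1`, `r2`, ...).
#' @return List of `tokenized_sentence` objects: `record_id`, `sentence`
#'   (index within the record), `tokens`, `kept` (logical mask).
#' @export
preprocess <- function(texts, tokenizer = whitespace_tokenizer,
                       filters = NULL,
                       terminators = "[。！？!?；;\n]+",
                       record_ids = NULL) {
  if (length(texts) == 0L) return(list())
  if (is.null(record_ids)) {
    record_ids <- names(texts) %||% paste0("r", seq_along(texts))
  }
  out <- list()
  for (i in seq_along(texts)) {
    pieces <- strsplit(texts[[i]], terminators)[[1]]
    pieces <- trimws(pieces)
    pieces <- pieces[nzchar(pieces)]
    for (j in seq_along(pieces)) {
      toks <- tokenizer(pieces[[j]])
      if (length(toks) == 0L) next
      out[[length(out) + 1L]] <- structure(
        list(record_id = record_ids[[i]], sentence = j, tokens = toks,
             kept = rep(TRUE, length(toks))),
        class = "tokenized_sentence")
    }
  }
  if (!is.null(filters)) out <- apply_filters(out, filters)
  out
}

#' Token filter configuration
#'
#' @param vocab Character vector of known components (typically the union
#'   of the position-model components and the embedding vocabulary), or
#'   `NULL` to skip the known-vocabulary filter.
#' @param common_top Fraction of the distinct corpus vocabulary, ranked by
#'   document frequency, treated as "extremely common" and masked
#'   (default 0.1%).
#' @param rare_min Minimum absolute corpus count for a token to survive the
#'   rare-word filter (default 2; use 0 or 1 to disable, appropriate for
#'   small corpora where most informative tokens occur once).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(vocab = NULL, common_top = 0.001, rare_min = 2L) {
  structure(list(vocab = vocab, common_top = common_top,
                 rare_min = rare_min),
            class = "filter_config")
}

apply_filters <- function(sentences, filters) {
  stopifnot(inherits(filters, "filter_config"))
  all_tokens <- unlist(lapply(sentences, `[[`, "tokens"), use.names = FALSE)
  counts <- table(all_tokens)
  # document frequency: number of records containing the token
  rec_tok <- unique(do.call(rbind, lapply(sentences, function(s) {
    data.frame(rec = s$record_id, tok = unique(s$tokens))
  })))
  df_counts <- table(rec_tok$tok)
  n_common <- floor(filters$common_top * length(df_counts))
  common <- if (n_common >= 1L) {
    names(sort(df_counts, decreasing = TRUE))[seq_len(n_common)]
  } else character()
  rare <- names(counts)[counts < filters$rare_min]
  lapply(sentences, function(s) {
    keep <- !(s$tokens %in% common) & !(s$tokens %in% rare)
    if (!is.null(filters$vocab)) keep <- keep & (s$tokens %in% filters$vocab)
    s$kept <- keep
    s
  })
}

#' @export
print.tokenized_sentence <- function(x, ...) {
  marks <- ifelse(x$kept, x$tokens, sprintf("(%s)", x$tokens))
  cat(sprintf("<tokenized_sentence> %s#%d: %s\n", x$record_id, x$sentence,
              paste(marks, collapse = " ")))
  invisible(x)
}

#' Candidate BIES/O labels per token
#'
#' A kept token known to the position model may take every BIES label whose
#' multinomial probability is strictly positive, plus `O` ("Other", outside
#' any phrase). A token unknown to the position model but present in the
#' embedding vocabulary may still act as a filler intermediate (`I`) inside
#' a span — colloquial sentences interleave such words with symptom
#' components — so it gets `{I, O}`. Everything else is `{O}` only.
#'
#' @param sentence A `tokenized_sentence`.
#' @param stats A [position_stats()] table.
#' @param embed_vocab Character vector of components with embeddings
#'   (default none).
#' @return Object of class `label_candidates`: list with `tokens` and
#'   `sets` (per-token character vectors of permissible labels).
#' @export
assign_labels <- function(sentence, stats, embed_vocab = character()) {
  stopifnot(inherits(sentence, "tokenized_sentence"),
            inherits(stats, "position_stats"))
  known <- rownames(stats)
  sets <- vector("list", length(sentence$tokens))
  for (i in seq_along(sentence$tokens)) {
    tok <- sentence$tokens[[i]]
    sets[[i]] <- if (sentence$kept[[i]] && tok %in% known) {
      cnt <- stats[tok, ]
      c(BIES_LEVELS[cnt > 0L], "O")
    } else if (tok %in% embed_vocab) {
      c("I", "O")
    } else {
      "O"
    }
  }
  structure(list(tokens = sentence$tokens, sets = sets),
            class = "label_candidates")
}

# Label-sequence grammar. A valid labeling is (O | S | B+ (I|O)* E+)*:
# free-floating O and S tokens, and spans that open with one or more B
# labels, continue with intermediate I (or skippable O) labels, and close
# with one or more E labels. Runs of B or E are collapsed afterwards by
# normalize_boundaries (leftmost B = begin, rightmost E = end).
.step <- function(state, label) {
  switch(state,
    OUT = switch(label, O = "OUT", S = "OUT", B = "BRUN", NA_character_),
    BRUN = switch(label, B = "BRUN", I = "MID", O = "MID", E = "ERUN",
                  NA_character_),
    MID = switch(label, I = "MID", O = "MID", E = "ERUN", NA_character_),
    ERUN = switch(label, E = "ERUN", O = "OUT", S = "OUT", B = "BRUN",
                  NA_character_)
  )
}

.accepting <- c("OUT", "ERUN")

#' Enumerate candidate segmentations
#'
#' Generates every labeling of the sentence drawn from the per-token
#' candidate sets that satisfies the subsequence grammar (non-overlapping
#' subsequences, each a single `S` token or a span opening with `B` and
#' closing with `E`), normalizes boundary runs, and de-duplicates. For
#' sentences longer than `max_exhaustive` a beam search over partial
#' labelings is used instead (requires `stats` for partial scoring); a beam
#' at least as wide as the number of valid labelings is equivalent to
#' exhaustive enumeration.
#'
#' @param candidates A [assign_labels()] result.
#' @param max_exhaustive Maximum sentence length for exhaustive enumeration.
#' @param beam_width Beam width used beyond `max_exhaustive`.
#' @param stats Optional [position_stats()] (needed for beam mode).
#' @return List of `candidate_segmentation` objects: `labels` (normalized)
#'   and `subsequences`, an integer matrix with columns `start`, `end`
#'   (1-based inclusive) and `single` (1 for a single-`S` subsequence).
#' @export
enumerate_segmentations <- function(candidates, max_exhaustive = 25L,
                                    beam_width = 64L, stats = NULL) {
  stopifnot(inherits(candidates, "label_candidates"))
  n <- length(candidates$tokens)
  if (n == 0L) return(list())
  raw <- if (n <= max_exhaustive) {
    enumerate_exhaustive(candidates$sets)
  } else {
    if (is.null(stats)) {
      stop_config("beam enumeration needs position statistics for scoring")
    }
    enumerate_beam(candidates, beam_width, stats)
  }
  norm <- lapply(raw, normalize_boundaries)
  keys <- vapply(norm, paste, character(1), collapse = "")
  norm <- norm[!duplicated(keys)]
  lapply(norm, function(lab) {
    structure(list(labels = lab, subsequences = parse_subsequences(lab)),
              class = "candidate_segmentation")
  })
}

enumerate_exhaustive <- function(sets) {
  n <- length(sets)
  acc <- vector("list", 0L)
  labels <- character(n)
  recurse <- function(i, state) {
    if (i > n) {
      if (state %in% .accepting) acc[[length(acc) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in sets[[i]]) {
      ns <- .step(state, lab)
      if (!is.na(ns)) {
        labels[i] <<- lab
        recurse(i + 1L, ns)
      }
    }
  }
  recurse(1L, "OUT")
  acc
}

enumerate_beam <- function(candidates, beam_width, stats) {
  sets <- candidates$sets
  toks <- candidates$tokens
  n <- length(sets)
  # partial: labels, state, done (score of closed subsequences),
  # open (pi_B of the leftmost B of the open span, NA if none)
  beam <- list(list(labels = character(0), state = "OUT", done = 0,
                    open = NA_real_))
  for (i in seq_len(n)) {
    nxt <- list()
    for (p in beam) {
      for (lab in sets[[i]]) {
        ns <- .step(p$state, lab)
        if (is.na(ns)) next
        q <- p
        q$labels <- c(q$labels, lab)
        q$state <- ns
        if (p$state %in% c("OUT", "ERUN")) {      # outside a span before i
          if (lab == "S") q$done <- q$done + pi_of(stats, toks[i], "S")
          if (lab == "B") q$open <- pi_of(stats, toks[i], "B")
        }
        if (ns == "ERUN" && p$state != "ERUN") {  # first E closes the span
          # pruning heuristic only: survivors are rescored exactly (after
          # boundary normalization) by pick_best_segmentation
          q$done <- q$done + q$open * pi_of(stats, toks[i], "E")
          q$open <- NA_real_
        }
        q$upper <- q$done + ifelse(is.na(q$open), 0, q$open)
        nxt[[length(nxt) + 1L]] <- q
      }
    }
    ord <- order(vapply(nxt, `[[`, numeric(1), "upper"), decreasing = TRUE)
    beam <- nxt[ord[seq_len(min(beam_width, length(ord)))]]
  }
  beam <- Filter(function(p) p$state %in% .accepting, beam)
  lapply(beam, `[[`, "labels")
}

#' Normalize boundary runs
#'
#' Within every span, consecutive `B` labels collapse to the leftmost (the
#' others become `I`) and consecutive `E` labels collapse to the rightmost.
#' Already-normalized labelings are returned unchanged.
#'
#' @param labels Character vector of labels forming a valid labeling, or a
#'   `candidate_segmentation`.
#' @return Object of the same kind with normalized labels.
#' @export
normalize_boundaries <- function(labels) {
  if (inherits(labels, "candidate_segmentation")) {
    lab <- normalize_boundaries(labels$labels)
    return(structure(list(labels = lab,
                          subsequences = parse_subsequences(lab)),
                     class = "candidate_segmentation"))
  }
  str <- paste(labels, collapse = "")
  m <- gregexpr("B+[IO]*E+", str)[[1]]
  if (m[1] == -1L) return(labels)
  out <- labels
  for (j in seq_along(m)) {
    a <- m[j]
    b <- a + attr(m, "match.length")[j] - 1L
    inner <- seq(a, b)
    mid <- inner[-c(1L, length(inner))]
    out[mid] <- ifelse(out[mid] == "O", "O", "I")
    out[a] <- "B"
    out[b] <- "E"
  }
  out
}

# subsequences of a normalized labeling: integer matrix with columns
# start, end (1-based inclusive) and single (0/1), ordered by start
parse_subsequences <- function(labels) {
  str <- paste(labels, collapse = "")
  spans <- gregexpr("B[IO]*E", str)[[1]]
  singles <- which(labels == "S")
  if (spans[1] == -1L) {
    starts <- ends <- integer(0)
  } else {
    starts <- as.integer(spans)
    ends <- starts + attr(spans, "match.length") - 1L
  }
  m <- cbind(start = c(starts, singles), end = c(ends, singles),
             single = c(integer(length(starts)),
                        rep(1L, length(singles))))
  m[order(m[, 1L]), , drop = FALSE]
}

#' Boundary score of a segmentation
#'
#' Sum over subsequences of the boundary score: \eqn{\pi_S} of the sole
#' token for a single, \eqn{\pi_B(\mathrm{first}) \cdot
#' \pi_E(\mathrm{last})} for a span.
#'
#' @param seg A `candidate_segmentation`.
#' @param tokens Character vector of sentence tokens.
#' @param stats A [position_stats()] table.
#' @return Non-negative real.
#' @export
score_segmentation <- function(seg, tokens, stats) {
  stopifnot(inherits(seg, "candidate_segmentation"))
  subs <- seg$subsequences
  if (nrow(subs) == 0L) return(0)
  sum(vapply(seq_len(nrow(subs)), function(r) {
    if (subs[r, "single"] == 1L) {
      pi_of(stats, tokens[subs[r, "start"]], "S")
    } else {
      pi_of(stats, tokens[subs[r, "start"]], "B") *
        pi_of(stats, tokens[subs[r, "end"]], "E")
    }
  }, numeric(1)))
}

#' Utility of an intermediate component
#'
#' Mean interaction score of the intermediate with the two boundary
#' components of its span: \eqn{\theta(w_i) = (I(w_1, w_i) + I(w_i, w_k)) /
#' 2}. When any of the three components lacks a neighbourhood distribution
#' the utility is 0 — an out-of-vocabulary intermediate is never kept at a
#' positive threshold, while a threshold of 0 keeps every intermediate
#' (matching the no-interaction ablation).
#'
#' @param model An `interaction_model` (or `NULL`).
#' @param w_first,w_mid,w_last The beginning, intermediate and end
#'   components.
#' @return Real in \eqn{[0, 1]}.
#' @export
utility <- function(model, w_first, w_mid, w_last) {
  if (is.null(model)) return(0)
  voc <- model$vocabulary
  if (!all(c(w_first, w_mid, w_last) %in% voc)) return(0)
  (interaction_score(model, w_first, w_mid) +
     interaction_score(model, w_mid, w_last)) / 2
}

#' Extraction configuration
#'
#' @param mode `"full"` (position model + interaction filtering),
#'   `"no-interaction"` (keep every intermediate inside the chosen
#'   boundaries) or `"no-position"` (group pairwise-interacting components
#'   with no boundary model).
#' @param delta Utility threshold for keeping an intermediate component
#'   (full mode) or interaction threshold for grouping (no-position mode).
#'   Default 0.2, the tuned operating point of the method.
#' @param score_floor A subsequence is emitted only if its own boundary
#'   score exceeds this floor (default 0, which preserves the plain argmax
#'   behaviour since candidate labels already require positive
#'   probabilities).
#' @param max_exhaustive,beam_width Passed to [enumerate_segmentations()].
#' @return Object of class `extract_config`.
#' @export
extract_config <- function(mode = c("full", "no-interaction", "no-position"),
                           delta = 0.2, score_floor = 0,
                           max_exhaustive = 25L, beam_width = 64L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, delta = delta, score_floor = score_floor,
                 max_exhaustive = max_exhaustive, beam_width = beam_width),
            class = "extract_config")
}

empty_extractions <- function() {
  data.frame(record_id = character(0), phrase = character(0),
              start = integer(0), end = integer(0),
              components = character(0), stringsAsFactors = FALSE)
}

#' Extract symptom phrases from a sentence
#'
#' Full mode: assigns candidate labels, enumerates valid segmentations,
#' picks the highest-scoring one (ties broken by larger token coverage,
#' then leftmost subsequence starts, then label string), normalizes
#' boundaries, and emits one extraction per subsequence. A `B-E` span with
#' no interior keeps both components; in a `B-I...I-E` span each interior
#' `I` component is kept only when its [utility()] reaches `delta`
#' (interior `O` tokens are skipped). `no-interaction` keeps every interior
#' `I`. `no-position` ignores boundaries entirely: kept components with
#' embeddings that pairwise interact (score >= `delta`) are connected into
#' groups, and every group of two or more components becomes a phrase.
#'
#' Spans in the output are 0-based half-open token indices;
#' `components` lists the 0-based indices of the concatenated tokens.
#'
#' @param sentence A `tokenized_sentence`.
#' @param stats A [position_stats()] table.
#' @param model An `interaction_model` (optional for
#'   `"no-interaction"` mode).
#' @param config An [extract_config()].
#' @return data.frame with columns `record_id`, `phrase`, `start`, `end`,
#'   `components` (comma-separated 0-based indices).
#' @export
extract_phrases <- function(sentence, stats, model = NULL,
                            config = extract_config()) {
  stopifnot(inherits(sentence, "tokenized_sentence"),
            inherits(config, "extract_config"))
  if (config$mode == "no-position") {
    return(extract_nopos(sentence, model, config))
  }
  embed_vocab <- if (!is.null(model)) model$vocabulary else character()
  cands <- assign_labels(sentence, stats, embed_vocab)
  segs <- enumerate_segmentations(cands, config$max_exhaustive,
                                  config$beam_width, stats)
  if (length(segs) == 0L) return(empty_extractions())
  best <- pick_best_segmentation(segs, sentence$tokens, stats)
  emit_extractions(best, sentence, stats, model, config)
}

pick_best_segmentation <- function(segs, tokens, stats) {
  scores <- vapply(segs, score_segmentation, numeric(1), tokens, stats)
  coverage <- vapply(segs, function(s) {
    if (nrow(s$subsequences) == 0L) return(0L)
    sum(s$subsequences[, "end"] - s$subsequences[, "start"] + 1L)
  }, integer(1))
  starts_key <- vapply(segs, function(s) {
    paste(sprintf("%04d", s$subsequences[, "start"]), collapse = "")
  }, character(1))
  label_key <- vapply(segs, function(s) paste(s$labels, collapse = ""),
                      character(1))
  ord <- order(-scores, -coverage, starts_key, label_key)
  segs[[ord[1]]]
}

emit_extractions <- function(seg, sentence, stats, model, config) {
  toks <- sentence$tokens
  subs <- seg$subsequences
  out <- empty_extractions()
  for (r in seq_len(nrow(subs))) {
    a <- unname(subs[r, "start"]); b <- unname(subs[r, "end"])
    if (subs[r, "single"] == 1L) {
      sc <- pi_of(stats, toks[a], "S")
      if (sc <= config$score_floor) next
      kept <- a
    } else {
      sc <- pi_of(stats, toks[a], "B") * pi_of(stats, toks[b], "E")
      if (sc <= config$score_floor) next
      interior <- setdiff(seq(a, b), c(a, b))
      ilab <- seg$labels[interior]
      ikept <- interior[ilab == "I"]
      if (config$mode == "full" && length(ikept)) {
        u <- vapply(ikept, function(i) {
          utility(model, toks[a], toks[i], toks[b])
        }, numeric(1))
        ikept <- ikept[u >= config$delta]
      }
      kept <- sort(c(a, ikept, b))
    }
    out <- rbind(out, data.frame(
      record_id = sentence$record_id,
      phrase = paste(toks[kept], collapse = ""),
      start = a - 1L, end = b,
      components = paste(kept - 1L, collapse = ","),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

extract_nopos <- function(sentence, model, config) {
  if (is.null(model)) {
    stop_config("no-position mode needs an interaction model")
  }
  toks <- sentence$tokens
  pos <- which(sentence$kept & toks %in% model$vocabulary)
  if (length(pos) < 2L) return(empty_extractions())
  # union-find over positions with pairwise interaction >= delta
  parent <- seq_along(pos)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(pos)) {
    for (j in seq_len(i - 1L)) {
      s <- interaction_score(model, toks[pos[i]], toks[pos[j]])
      if (s >= config$delta) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(pos), find, integer(1))
  out <- empty_extractions()
  for (g in unique(roots)) {
    members <- pos[roots == g]
    if (length(members) < 2L) next
    out <- rbind(out, data.frame(
      record_id = sentence$record_id,
      phrase = paste(toks[members], collapse = ""),
      start = min(members) - 1L, end = max(members),
      components = paste(members - 1L, collapse = ","),
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract phrases from a whole preprocessed corpus
#'
#' @param sentences List of `tokenized_sentence` objects (from
#'   [preprocess()]).
#' @inheritParams extract_phrases
#' @return data.frame of extractions (one row per extracted phrase).
#' @export
extract_corpus <- function(sentences, stats, model = NULL,
                           config = extract_config()) {
  res <- lapply(sentences, extract_phrases, stats = stats, model = model,
                config = config)
  out <- do.call(rbind, c(list(empty_extractions()), res))
  rownames(out) <- NULL
  out
}
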