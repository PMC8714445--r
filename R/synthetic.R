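#' Synthetic benchmark generator configuration
#'
#' Generates dictionaries, corpora and gold annotations with known
#' compositional structure, so that every pipeline stage can be tested
#' without real clinical text. Components are opaque ASCII symbols grouped
#' into `n_topics` disjoint topics; each component has a positional role
#' with a known BIES multinomial:
#' \describe{
#'   \item{begin}{\eqn{\pi_B} drawn in `[0.65, 0.9]`, remainder on
#'     \eqn{\pi_I} (boundary words also occur mid-phrase);}
#'   \item{end}{mirror image on \eqn{\pi_E};}
#'   \item{interior}{\eqn{\pi_I = 1};}
#'   \item{single}{\eqn{\pi_S} drawn in `[0.7, 0.9]`, remainder on
#'     \eqn{\pi_I}.}
#' }
#' Filler and background tokens come from disjoint vocabularies that never
#' enter the dictionary: fillers are inserted inside spans (they emulate
#' colloquial interruptions and are never part of the gold phrase),
#' background tokens pad the sentence around spans.
#'
#' @param n_topics Number of disjoint semantic topics.
#' @param n_begin,n_end,n_interior,n_single Components per role \emph{per
#'   topic}.
#' @param n_filler,n_background Sizes of the filler and background
#'   vocabularies.
#' @param n_phrases Target dictionary size (the realized size fluctuates
#'   slightly around it; see [generate_dictionary()]).
#' @param interior_mean Mean number of interior components per dictionary
#'   span.
#' @param n_sentences Corpus size in sentences.
#' @param phrases_per_sentence Probability weights for embedding 0, 1 or 2
#'   phrases in a sentence.
#' @param single_rate Probability that an embedded phrase is a singleton.
#' @param corpus_interior_mean Mean interiors per embedded (recombined)
#'   span.
#' @param filler_rate Probability of inserting a filler token at each
#'   interior gap of an embedded span.
#' @param distractor_rate Probability of inserting one cross-topic
#'   component (position-legal as an interior, semantically incompatible)
#'   into an embedded span.
#' @param mixing Scale of the off-role position mass in \eqn{[0, 1]}: with
#'   the default 0.25 boundary-capable words also occur mid-phrase (their
#'   segmentation is genuinely ambiguous, as in real compositional
#'   phrases), while 0 gives pure positional roles (every component is
#'   unambiguous, so a correct pipeline can segment noise-free text
#'   exactly).
#' @param recombine If `TRUE`, embedded phrases are re-composed from
#'   components in position-legal order (often unseen as whole phrases);
#'   if `FALSE`, dictionary phrases are embedded verbatim.
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_topics = 2L, n_begin = 30L, n_end = 30L,
                             n_interior = 25L, n_single = 15L,
                             n_filler = 30L, n_background = 40L,
                             n_phrases = 400L, interior_mean = 1.0,
                             n_sentences = 200L,
                             phrases_per_sentence = c(0.1, 0.6, 0.3),
                             single_rate = 0.2,
                             corpus_interior_mean = 1.2,
                             filler_rate = 0.3, distractor_rate = 0.15,
                             mixing = 0.25, recombine = TRUE, seed = 1L) {
  stopifnot(n_topics >= 1L, n_phrases >= 1L,
            all(phrases_per_sentence >= 0), sum(phrases_per_sentence) > 0,
            filler_rate >= 0, filler_rate <= 1,
            distractor_rate >= 0, distractor_rate <= 1)
  if (n_begin + n_end + n_interior + n_single < 1L) {
    stop_config("at least one symptom component per topic is required")
  }
  structure(as.list(environment()), class = "generator_config")
}

rand_tokens <- function(n, len, alphabet, prefix = "") {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out)), function(i) {
      paste0(prefix, paste(sample(alphabet, len, replace = TRUE),
                           collapse = ""))
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

# role -> true BIES multinomial with per-component jitter; `mixing` scales
# the off-role (intermediate) mass, 0 = pure positional roles
role_pi <- function(role, mixing = 0.25) {
  off <- function(lo, hi) mixing * runif(1, lo, hi)
  switch(role,
    begin = { m <- off(0.7, 1.4); c(B = 1 - m, I = m, E = 0, S = 0) },
    end = { m <- off(0.7, 1.4); c(B = 0, I = m, E = 1 - m, S = 0) },
    interior = c(B = 0, I = 1, E = 0, S = 0),
    single = { m <- off(0.4, 1.2); c(B = 0, I = m, E = 0, S = 1 - m) }
  )
}

#' Generate a synthetic symptom dictionary
#'
#' Each component's position occurrences are drawn directly from its known
#' multinomial: components are sampled uniformly within their topic, each
#' draw emits a (component, position) token, and the tokens are assembled
#' into phrases — `S` tokens become singleton phrases, each `B` token is
#' paired with an `E` token, and `I` tokens are distributed uniformly among
#' the spans. Only the small random surplus of unpaired boundary tokens is
#' discarded, so the per-component empirical position frequencies are
#' unbiased estimates of the generating multinomials (enabling parameter-
#' recovery tests). The number of draws is calibrated so the realized
#' phrase count is close to `n_phrases`.
#'
#' @param config A [generator_config()].
#' @return List with `phrases` (list of [symptom_phrase()]), `topic`
#'   (integer topic per phrase), and `truth`: `pi` (true multinomial
#'   matrix, rows = components), `role`, `topic_of`, `fillers`,
#'   `background`.
#' @export
generate_dictionary <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  per_topic <- config$n_begin + config$n_end + config$n_interior +
    config$n_single
  n_comp <- per_topic * config$n_topics
  comps <- rand_tokens(n_comp, 4L, letters)
  roles <- rep(rep(c("begin", "end", "interior", "single"),
                   c(config$n_begin, config$n_end, config$n_interior,
                     config$n_single)),
               config$n_topics)
  topic_of <- rep(seq_len(config$n_topics), each = per_topic)
  pi_true <- t(vapply(roles, role_pi, numeric(4), mixing = config$mixing))
  rownames(pi_true) <- comps
  names(roles) <- comps
  names(topic_of) <- comps
  fillers <- rand_tokens(config$n_filler, 3L, LETTERS, prefix = "F")
  background <- rand_tokens(config$n_background, 3L, LETTERS, prefix = "Z")

  phrases <- list()
  topic_vec <- integer(0)
  target_per_topic <- config$n_phrases / config$n_topics
  for (t in seq_len(config$n_topics)) {
    members <- comps[topic_of == t]
    pt <- pi_true[members, , drop = FALSE]
    # expected phrases per draw: singles + matched B/E pairs
    yield <- mean(pt[, "S"]) + min(mean(pt[, "B"]), mean(pt[, "E"]))
    # extra draws so spans reach roughly interior_mean interiors each
    n_draws <- ceiling(target_per_topic / max(yield, 1e-6))
    drawn <- sample(members, n_draws, replace = TRUE)
    pos <- vapply(drawn, function(cp) {
      sample(BIES_LEVELS, 1L, prob = pi_true[cp, ])
    }, character(1))
    singles <- drawn[pos == "S"]
    bs <- drawn[pos == "B"]; es <- drawn[pos == "E"]; is_ <- drawn[pos == "I"]
    m <- min(length(bs), length(es))
    for (s in singles) {
      phrases[[length(phrases) + 1L]] <-
        symptom_phrase(s, s, "word")
      topic_vec <- c(topic_vec, t)
    }
    if (m > 0L) {
      assign_to <- if (length(is_)) sample.int(m, length(is_), replace = TRUE)
                   else integer(0)
      for (j in seq_len(m)) {
        mid <- is_[assign_to == j]
        cc <- c(bs[j], mid, es[j])
        phrases[[length(phrases) + 1L]] <-
          symptom_phrase(paste(cc, collapse = " "), cc, "word")
        topic_vec <- c(topic_vec, t)
      }
    }
  }
  ord <- sample.int(length(phrases))  # interleave topics
  list(phrases = phrases[ord], topic = topic_vec[ord],
       truth = list(pi = pi_true, role = roles, topic_of = topic_of,
                    fillers = fillers, background = background),
       config = config)
}

sample_weighted <- function(members, weights, n = 1L) {
  members[sample.int(length(members), n, replace = TRUE, prob = weights)]
}

#' Generate a synthetic consultation corpus with gold annotations
#'
#' Each sentence embeds 0 or more symptom phrases, padded and interrupted
#' by noise: background tokens around spans, out-of-vocabulary filler
#' tokens inside spans (rate `filler_rate` per interior gap), and
#' cross-topic distractor components (rate `distractor_rate` per span) that
#' are position-legal interiors but semantically incompatible with the
#' span's boundaries. With `recombine = TRUE` the embedded phrases are
#' fresh position-legal compositions (mostly unseen in the dictionary);
#' otherwise dictionary phrases are used verbatim. The gold table records
#' the intended phrase (symptom components only — never fillers or
#' distractors).
#'
#' @param dict Result of [generate_dictionary()].
#' @param config A [generator_config()] (defaults to the one inside
#'   `dict`).
#' @return List with `texts` (character vector of sentences, tokens
#'   space-separated, names = record ids), `gold` (data.frame `record_id`,
#'   `phrase`), and `gold_spans` (token index bookkeeping, 0-based
#'   half-open).
#' @export
generate_corpus <- function(dict, config = dict$config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1000003L)

  truth <- dict$truth
  comps <- rownames(truth$pi)
  nq <- length(config$phrases_per_sentence)
  texts <- character(config$n_sentences)
  ids <- sprintf("r%04d", seq_len(config$n_sentences))
  gold <- list()
  spans <- list()
  for (i in seq_len(config$n_sentences)) {
    q <- sample.int(nq, 1L, prob = config$phrases_per_sentence) - 1L
    toks <- sample(truth$background, sample.int(3L, 1L) - 1L, replace = TRUE)
    for (p in seq_len(q)) {
      t <- sample.int(config$n_topics, 1L)
      members <- comps[truth$topic_of == t]
      pt <- truth$pi[members, , drop = FALSE]
      symptom <- build_span(dict, members, pt, t, config)
      noisy <- insert_noise(symptom, t, truth, comps, config)
      a <- length(toks)
      toks <- c(toks, noisy)
      gold[[length(gold) + 1L]] <- data.frame(
        record_id = ids[i], phrase = paste(symptom, collapse = ""),
        stringsAsFactors = FALSE)
      spans[[length(spans) + 1L]] <- data.frame(
        record_id = ids[i], start = a, end = a + length(noisy),
        stringsAsFactors = FALSE)
      toks <- c(toks, sample(truth$background, sample.int(3L, 1L) - 1L,
                             replace = TRUE))
    }
    if (length(toks) == 0L) {
      toks <- sample(truth$background, 2L, replace = TRUE)
    }
    texts[i] <- paste(toks, collapse = " ")
  }
  names(texts) <- ids
  list(texts = texts,
       gold = do.call(rbind, c(list(data.frame(record_id = character(0),
                                               phrase = character(0))),
                               gold)),
       gold_spans = do.call(rbind, c(list(data.frame(record_id = character(0),
                                                     start = integer(0),
                                                     end = integer(0))),
                                     spans)))
}

# symptom components of one embedded phrase (no noise)
build_span <- function(dict, members, pt, t, config) {
  if (!config$recombine) {
    cand <- which(dict$topic == t)
    return(dict$phrases[[sample(cand, 1L)]]$components)
  }
  if (runif(1) < config$single_rate && any(pt[, "S"] > 0)) {
    return(sample_weighted(members, pt[, "S"]))
  }
  if (all(pt[, "B"] == 0) || all(pt[, "E"] == 0)) {
    return(sample_weighted(members, pt[, "S"]))
  }
  k <- rpois(1, config$corpus_interior_mean)
  mid <- if (k > 0L && any(pt[, "I"] > 0)) {
    sample_weighted(members, pt[, "I"], k)
  } else character(0)
  c(sample_weighted(members, pt[, "B"]), mid,
    sample_weighted(members, pt[, "E"]))
}

# fillers at interior gaps, plus at most one cross-topic distractor
insert_noise <- function(symptom, t, truth, comps, config) {
  n <- length(symptom)
  if (n < 2L) return(symptom)
  inserts <- vector("list", n - 1L)  # material after position g
  for (g in seq_len(n - 1L)) {
    if (runif(1) < config$filler_rate) {
      inserts[[g]] <- sample(truth$fillers, 1L)
    } else inserts[[g]] <- character(0)
  }
  if (config$n_topics > 1L && runif(1) < config$distractor_rate) {
    others <- comps[truth$topic_of != t & truth$pi[comps, "I"] > 0]
    if (length(others)) {
      g <- sample.int(n - 1L, 1L)
      inserts[[g]] <- c(inserts[[g]], sample(others, 1L))
    }
  }
  out <- symptom[1]
  for (g in seq_len(n - 1L)) {
    out <- c(out, inserts[[g]], symptom[g + 1L])
  }
  out
}

#' Write a generated benchmark to plain-text files
#'
#' Writes `dictionary.txt` (one phrase per line), `corpus.txt` (one record
#' per line, tab-separated record id and text), `gold.tsv` (record id,
#' phrase) and `truth.tsv` (component, role, topic, true multinomial) into
#' a directory.
#'
#' @param dict Result of [generate_dictionary()].
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(dict, corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(vapply(dict$phrases, `[[`, character(1), "raw"),
             file.path(dir, "dictionary.txt"), useBytes = TRUE)
  writeLines(sprintf("%s\t%s", names(corpus$texts), corpus$texts),
             file.path(dir, "corpus.txt"), useBytes = TRUE)
  write.table(corpus$gold, file.path(dir, "gold.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth_df <- data.frame(component = rownames(dict$truth$pi),
                         role = unname(dict$truth$role),
                         topic = unname(dict$truth$topic_of),
                         pi_B = dict$truth$pi[, "B"],
                         pi_I = dict$truth$pi[, "I"],
                         pi_E = dict$truth$pi[, "E"],
                         pi_S = dict$truth$pi[, "S"])
  write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
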