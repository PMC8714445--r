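test_that("preprocessing splits sentences and applies token filters", {
  out <- preprocess(c(r1 = "A. B!", r2 = "C"), character_tokenizer,
                    terminators = "[.!]")
  expect_length(out, 3L)
  expect_equal(out[[1]]$tokens, "A")
  expect_equal(out[[1]]$record_id, "r1")
  expect_equal(out[[2]]$sentence, 2L)
  expect_identical(preprocess(character()), list())

  # known-vocabulary, common-word and rare-word filters set the kept mask
  texts <- c(rep("the cough", 300), rep("the fever", 300),
             "the unknownword cough once")
  names(texts) <- paste0("r", seq_along(texts))
  sents <- preprocess(texts, whitespace_tokenizer,
                      filters = filter_config(vocab = c("the", "cough",
                                                        "fever", "once"),
                                              common_top = 0.2,
                                              rare_min = 2L))
  last <- sents[[length(sents)]]
  expect_equal(last$tokens,
               c("the", "unknownword", "cough", "once"))
  # "the" tops the document-frequency ranking -> masked; OOV masked;
  # "once" occurs only once in the corpus -> masked by the rare floor
  expect_equal(last$kept, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("candidate labels reflect positive position probabilities", {
  stats <- stats_from(c("a", "b", "c"), c("a", "c"), "f", c("a", "f", "c"))
  s <- make_sentence(c("a", "f", "c", "x", "g"),
                     kept = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cand <- assign_labels(s, stats, embed_vocab = c("x", "g"))
  expect_setequal(cand$sets[[1]], c("B", "O"))        # a: only B observed
  expect_setequal(cand$sets[[2]], c("I", "S", "O"))   # f: S and I observed
  expect_setequal(cand$sets[[3]], c("E", "O"))        # c: only E observed
  expect_setequal(cand$sets[[4]], c("I", "O"))        # embedding-only filler
  expect_setequal(cand$sets[[5]], c("I", "O"))        # masked but embedded
})

test_that("enumeration matches a brute-force label-product filter", {
  stats <- stats_from(c("a", "b", "c"), "f")
  for (sets in list(list(c("B", "O"), c("I", "O"), c("E", "O")),
                    list(c("S", "O")),
                    list("O", "O"),
                    list(c("B", "S", "O"), c("B", "I", "E", "O"),
                         c("E", "O"), c("S", "O")))) {
    toks <- paste0("t", seq_along(sets))
    cand <- structure(list(tokens = toks, sets = sets),
                      class = "label_candidates")
    segs <- enumerate_segmentations(cand)
    grid <- do.call(expand.grid,
                    c(rev(sets), list(stringsAsFactors = FALSE)))
    labstr <- do.call(paste0, grid[, rev(seq_along(sets)), drop = FALSE])
    valid <- labstr[grepl("^(O|S|B+[IO]*E+)*$", labstr)]
    # normalized, de-duplicated labelings must coincide as sets
    norm <- unique(vapply(strsplit(valid, ""), function(l) {
      paste(normalize_boundaries(l), collapse = "")
    }, character(1)))
    got <- vapply(segs, function(s) paste(s$labels, collapse = ""),
                  character(1))
    expect_setequal(got, norm)
  }
  # spec'd counts: {O}-only -> one empty labeling; {S,O} -> two
  one <- enumerate_segmentations(structure(
    list(tokens = "t", sets = list("O")), class = "label_candidates"))
  expect_length(one, 1L)
  two <- enumerate_segmentations(structure(
    list(tokens = "t", sets = list(c("S", "O"))),
    class = "label_candidates"))
  expect_length(two, 2L)
})

test_that("boundary normalization collapses B and E runs", {
  expect_equal(normalize_boundaries(c("B", "B", "E")), c("B", "I", "E"))
  expect_equal(normalize_boundaries(c("B", "E", "E")), c("B", "I", "E"))
  expect_equal(normalize_boundaries(c("B", "I", "E")), c("B", "I", "E"))
  expect_equal(normalize_boundaries(c("B", "O", "E")), c("B", "O", "E"))
  expect_equal(normalize_boundaries(c("O", "S", "O")), c("O", "S", "O"))
  expect_equal(normalize_boundaries(c("B", "B", "O", "E", "E", "S")),
               c("B", "I", "O", "I", "E", "S"))
})

test_that("segmentation scores follow the boundary scoring function", {
  # pi_S(f) = 0.9 via 9 singleton + 1 interior uses; pi_B(a)=0.8, pi_E(c)=0.5
  phr <- c(rep(list(c("f")), 9), list(c("x", "f", "y")),
           rep(list(c("a", "c")), 4), list(c("c", "a")),
           rep(list(c("x", "c")), 3), list(c("c", "y")), list(c("x", "c")))
  stats <- position_stats(annotate_dictionary(
    do.call(phrase_list, phr)))
  expect_equal(unname(position_probabilities(stats, "f")["S"]), 0.9)
  toks <- c("f", "a", "x", "c")
  seg <- structure(list(
    labels = c("S", "B", "I", "E"),
    subsequences = cbind(start = c(1L, 2L), end = c(1L, 4L),
                         single = c(1L, 0L))),
    class = "candidate_segmentation")
  pb <- compsym:::pi_of(stats, "a", "B")
  pe <- compsym:::pi_of(stats, "c", "E")
  expect_equal(score_segmentation(seg, toks, stats), 0.9 + pb * pe)
})

test_that("utility is the mean boundary interaction, 0 when OOV", {
  m <- manual_model(list(w1 = c(1, 0, 0), mid = c(0.5, 0.5, 0),
                         wk = c(1, 0, 0), far = c(0, 0, 1)))
  i1 <- interaction_score(m, "w1", "mid")
  i2 <- interaction_score(m, "mid", "wk")
  expect_equal(utility(m, "w1", "mid", "wk"), (i1 + i2) / 2)
  expect_equal(utility(m, "w1", "w1", "wk"),
               (1 + interaction_score(m, "w1", "wk")) / 2)
  expect_equal(utility(m, "w1", "absent", "wk"), 0)
  expect_equal(utility(NULL, "w1", "mid", "wk"), 0)
})

test_that("a span with weak interiors keeps only compatible components", {
  # analogue of a colloquial sentence: B f1 good f2 E where the fillers sit
  # in a remote embedding neighbourhood
  stats <- stats_from(c("b1", "g", "e1"), c("b1", "e1"))
  m <- manual_model(list(b1 = c(1, 0, 0, 0), e1 = c(1, 0, 0, 0),
                         g = c(1, 0, 0, 0), f1 = c(0, 1, 0, 0),
                         f2 = c(0, 0, 1, 0)))
  s <- make_sentence(c("b1", "f1", "g", "f2", "e1"),
                     kept = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  got <- extract_phrases(s, stats, m, extract_config(delta = 0.5))
  expect_equal(got$phrase, "b1ge1")
  expect_equal(got$start, 0L)
  expect_equal(got$end, 5L)
  expect_equal(got$components, "0,2,4")
  # no-interaction mode keeps the fillers
  got_ni <- extract_phrases(s, stats, m,
                            extract_config(mode = "no-interaction"))
  expect_equal(got_ni$phrase, "b1f1gf2e1")
})

test_that("training phrases are recovered verbatim from clean sentences", {
  stats <- stats_from(c("b1", "m1", "e1"), c("b2", "e2"), "s1")
  s <- make_sentence(c("zz", "b1", "m1", "e1", "zz"),
                     kept = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  got <- extract_phrases(s, stats, NULL,
                         extract_config(mode = "no-interaction"))
  expect_equal(got$phrase, "b1m1e1")
  s2 <- make_sentence("s1")
  expect_equal(extract_phrases(s2, stats)$phrase, "s1")
})

test_that("extraction equals the brute-force oracle on random sentences", {
  # a smaller rehearsal of the exhaustive-oracle acceptance check
  n_cases <- 60L
  set.seed(2024)
  seeds <- sample.int(10000L, 20L)
  case <- 0L
  for (ws in seeds) {
    w <- random_world(ws)
    params <- w$model$params
    while (case < n_cases) {
      len <- sample(2:8, 1)
      toks <- sample(w$tokens_pool, len, replace = TRUE)
      kept <- runif(len) > 0.1
      sizes <- vapply(oracle_sets(toks, kept, w$pim, w$nbhd), length, 1L)
      if (prod(sizes) > 6000) next
      s <- make_sentence(toks, kept)
      got <- extract_phrases(s, w$stats, w$model,
                             extract_config(delta = 0.35))
      want <- oracle_extract(toks, kept, w$pim, w$nbhd,
                             nu = params$nu, gamma = params$gamma,
                             delta = 0.35)
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got, want)
      case <- case + 1L
      if (case %% 10L == 0L) break  # rotate worlds
    }
    if (case >= n_cases) break
  }
  expect_gte(case, n_cases)
})

test_that("delta 0 reduces full mode to the no-interaction ablation", {
  set.seed(5)
  w <- random_world(77)
  for (i in 1:25) {
    len <- sample(2:7, 1)
    toks <- sample(w$tokens_pool, len, replace = TRUE)
    s <- make_sentence(toks)
    full0 <- extract_phrases(s, w$stats, w$model,
                             extract_config(mode = "full", delta = 0))
    noint <- extract_phrases(s, w$stats, w$model,
                             extract_config(mode = "no-interaction"))
    expect_identical(full0, noint)
  }
})

test_that("raising delta never keeps more interior components", {
  set.seed(6)
  w <- random_world(88)
  n_components <- function(df) {
    if (nrow(df) == 0L) return(0L)
    sum(lengths(strsplit(df$components, ",")))
  }
  for (i in 1:15) {
    toks <- sample(w$tokens_pool, sample(3:7, 1), replace = TRUE)
    s <- make_sentence(toks)
    kept_count <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(d) {
      n_components(extract_phrases(s, w$stats, w$model,
                                   extract_config(delta = d)))
    }, numeric(1))
    expect_true(all(diff(kept_count) <= 0))
  }
})

test_that("extracted spans never overlap and extraction is deterministic", {
  set.seed(8)
  w <- random_world(99)
  for (i in 1:20) {
    toks <- sample(w$tokens_pool, sample(4:8, 1), replace = TRUE)
    s <- make_sentence(toks)
    a <- extract_phrases(s, w$stats, w$model, extract_config())
    b <- extract_phrases(s, w$stats, w$model, extract_config())
    expect_identical(a, b)
    if (nrow(a) > 1L) {
      expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
    }
  }
})

test_that("a wide-enough beam reproduces exhaustive enumeration", {
  w <- random_world(123)
  toks <- c("b1", "m1", "s1", "e1", "f1")
  s <- make_sentence(toks)
  cand <- assign_labels(s, w$stats, embed_vocab = rownames(w$nbhd))
  exact <- enumerate_segmentations(cand, max_exhaustive = 25L)
  beamed <- enumerate_segmentations(cand, max_exhaustive = 2L,
                                    beam_width = 10000L, stats = w$stats)
  key <- function(segs) sort(vapply(segs, function(x) {
    paste(x$labels, collapse = "")
  }, character(1)))
  expect_identical(key(beamed), key(exact))
})

test_that("no-position mode groups pairwise-interacting components", {
  m <- manual_model(list(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0.9, 0.1, 0),
                         z = c(0, 0, 1)))
  stats <- stats_from(c("a", "b"))  # irrelevant for this mode
  s <- make_sentence(c("a", "z", "b", "c"))
  got <- extract_phrases(s, stats, m,
                         extract_config(mode = "no-position", delta = 0.5))
  expect_equal(got$phrase, "abc")   # a-b-c connected; z isolated
  expect_equal(got$start, 0L)
  expect_equal(got$end, 4L)
  # singletons are not emitted
  s2 <- make_sentence(c("a", "z"))
  got2 <- extract_phrases(s2, stats, m,
                          extract_config(mode = "no-position", delta = 0.5))
  expect_equal(nrow(got2), 0L)
})
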