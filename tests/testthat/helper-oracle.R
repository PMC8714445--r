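# Brute-force reference extractor, kept deliberately independent of the
# package internals: it enumerates the full label product, filters valid
# labelings with a regex over the subsequence grammar, scores them directly
# from the probability matrix, applies the documented tie-break rule
# (score, then coverage, then leftmost starts, then label string), and
# filters intermediates with its own divergence arithmetic.

oracle_kl <- function(p, q) {
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  0.5 * oracle_kl(p, m) + 0.5 * oracle_kl(q, m)
}

oracle_interaction <- function(nbhd, a, b, nu, gamma) {
  min(1, exp(-nu * oracle_jsd(nbhd[a, ], nbhd[b, ]) + gamma))
}

oracle_utility <- function(nbhd, w1, wm, wk, nu, gamma) {
  if (!all(c(w1, wm, wk) %in% rownames(nbhd))) return(0)
  (oracle_interaction(nbhd, w1, wm, nu, gamma) +
     oracle_interaction(nbhd, wm, wk, nu, gamma)) / 2
}

# candidate label sets per the documented contract
oracle_sets <- function(tokens, kept, pim, nbhd) {
  lapply(seq_along(tokens), function(i) {
    tok <- tokens[i]
    if (kept[i] && tok %in% rownames(pim)) {
      c(c("B", "I", "E", "S")[pim[tok, ] > 0], "O")
    } else if (tok %in% rownames(nbhd)) {
      c("I", "O")
    } else "O"
  })
}

oracle_extract <- function(tokens, kept, pim, nbhd, nu, gamma, delta,
                           mode = "full", record_id = "t1") {
  n <- length(tokens)
  sets <- oracle_sets(tokens, kept, pim, nbhd)
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_len(n)), drop = FALSE]
  labstr <- do.call(paste0, grid)
  labstr <- labstr[grepl("^(O|S|B+[IO]*E+)*$", labstr)]
  pi_get <- function(tok, lab) {
    if (!tok %in% rownames(pim)) 0 else pim[tok, lab]
  }
  best <- NULL
  for (ls in labstr) {
    lab <- strsplit(ls, "")[[1]]
    m <- gregexpr("B+[IO]*E+", ls)[[1]]
    spans <- if (m[1] == -1L) NULL else
      cbind(as.integer(m), as.integer(m) + attr(m, "match.length") - 1L)
    singles <- which(lab == "S")
    # per-subsequence scores in start order (same summation order as the
    # package, so exact ties stay exact)
    subs <- rbind(
      if (!is.null(spans)) data.frame(start = spans[, 1], end = spans[, 2]),
      if (length(singles)) data.frame(start = singles, end = singles))
    score <- 0
    if (!is.null(subs)) {
      subs <- subs[order(subs$start), , drop = FALSE]
      score <- sum(vapply(seq_len(nrow(subs)), function(r) {
        a <- subs$start[r]; b <- subs$end[r]
        if (a == b && lab[a] == "S") pi_get(tokens[a], "S")
        else pi_get(tokens[a], "B") * pi_get(tokens[b], "E")
      }, numeric(1)))
    }
    coverage <- if (is.null(subs)) 0L else sum(subs$end - subs$start + 1L)
    starts_key <- if (is.null(subs)) "" else
      paste(sprintf("%04d", subs$start), collapse = "")
    nl <- lab
    if (!is.null(spans)) {
      for (r in seq_len(nrow(spans))) {
        a <- spans[r, 1]; b <- spans[r, 2]
        if (b - a >= 2L) {
          mid <- (a + 1L):(b - 1L)
          nl[mid] <- ifelse(nl[mid] == "O", "O", "I")
        }
        nl[a] <- "B"; nl[b] <- "E"
      }
    }
    cand <- list(score = score, coverage = coverage, sk = starts_key,
                 lk = paste(nl, collapse = ""), nl = nl, subs = subs)
    if (is.null(best) || oracle_better(cand, best)) best <- cand
  }
  oracle_emit(best, tokens, nbhd, nu, gamma, delta, mode, record_id)
}

oracle_better <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$coverage != b$coverage) return(a$coverage > b$coverage)
  if (a$sk != b$sk) return(a$sk < b$sk)
  a$lk < b$lk
}

oracle_emit <- function(best, tokens, nbhd, nu, gamma, delta, mode,
                        record_id) {
  out <- data.frame(record_id = character(0), phrase = character(0),
                    start = integer(0), end = integer(0),
                    components = character(0), stringsAsFactors = FALSE)
  subs <- best$subs
  if (is.null(subs)) return(out)
  for (r in seq_len(nrow(subs))) {
    a <- subs$start[r]; b <- subs$end[r]
    if (a == b) {
      kept_idx <- a
    } else {
      interior <- setdiff(seq(a, b), c(a, b))
      ikept <- interior[best$nl[interior] == "I"]
      if (mode == "full" && length(ikept)) {
        u <- vapply(ikept, function(i) {
          oracle_utility(nbhd, tokens[a], tokens[i], tokens[b], nu, gamma)
        }, numeric(1))
        ikept <- ikept[u >= delta]
      }
      kept_idx <- sort(c(a, ikept, b))
    }
    out <- rbind(out, data.frame(
      record_id = record_id,
      phrase = paste(tokens[kept_idx], collapse = ""),
      start = a - 1L, end = b,
      components = paste(kept_idx - 1L, collapse = ","),
      stringsAsFactors = FALSE))
  }
  out
}

# random test world: a small dictionary inducing mixed position stats and a
# random neighbourhood matrix over dictionary components plus filler words
random_world <- function(seed) {
  set.seed(seed)
  vocab <- c("b1", "b2", "m1", "m2", "e1", "e2", "s1", "s2")
  fillers <- c("f1", "f2")
  dict <- list()
  for (i in 1:12) {
    len <- sample(1:4, 1)
    cc <- if (len == 1) sample(c("s1", "s2"), 1) else
      c(sample(c("b1", "b2", "s1"), 1),
        if (len > 2) sample(c("m1", "m2", "s2", "e1"), len - 2,
                            replace = TRUE) else character(0),
        sample(c("e1", "e2", "m1"), 1))
    dict[[i]] <- symptom_phrase(paste(cc, collapse = " "), cc, "word")
  }
  stats <- position_stats(annotate_dictionary(dict))
  pim <- position_probabilities(stats)
  nb_vocab <- c(vocab, fillers)
  nb <- matrix(runif(length(nb_vocab) * 4), nrow = length(nb_vocab))
  nb <- nb / rowSums(nb)
  rownames(nb) <- nb_vocab
  list(stats = stats, pim = pim, nbhd = nb,
       model = interaction_model(nb, interaction_params(seed = seed)),
       tokens_pool = c(vocab, fillers, "zz1", "zz2"))
}
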