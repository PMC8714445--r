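#' Dictionary-matching baselines
#'
#' Classical dictionary baselines against which the composition-driven
#' recognizer is compared. Both operate on component sequences, so at
#' character granularity they reduce to plain substring matching.
#'
#' `baseline_dictionary_lookup()` emits every maximal exact occurrence of a
#' dictionary phrase in the token sequence; overlapping candidates are
#' resolved longest-leftmost (scan left to right, take the longest match at
#' each position, jump past it).
#'
#' `baseline_bdmm()` is bidirectional maximal matching: forward maximal
#' matching (longest dictionary entry at each position, scanning left to
#' right, single-token segment when nothing matches) and reverse maximal
#' matching (same, right to left) are both run, and the direction with
#' fewer segments wins; ties prefer fewer single-component segments, then
#' the forward result. Segments that are dictionary phrases become the
#' extractions.
#'
#' @param sentence A `tokenized_sentence` (all tokens are used; the kept
#'   mask is ignored, as these baselines have no notion of filtering).
#' @param dictionary List of [symptom_phrase()] objects.
#' @return data.frame of extractions in the same shape as
#'   [extract_phrases()] (0-based half-open spans).
#' @name baselines
NULL

dict_index <- function(dictionary) {
  keys <- vapply(dictionary, function(p) {
    paste(p$components, collapse = "\u1f")
  }, character(1))
  lens <- vapply(dictionary, function(p) length(p$components), integer(1))
  list(keys = unique(keys), max_len = max(lens))
}

seq_key <- function(tokens) paste(tokens, collapse = "\u1f")

#' @rdname baselines
#' @export
baseline_dictionary_lookup <- function(sentence, dictionary) {
  stopifnot(inherits(sentence, "tokenized_sentence"))
  idx <- dict_index(dictionary)
  toks <- sentence$tokens
  n <- length(toks)
  out <- empty_extractions()
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (len in rev(seq_len(min(idx$max_len, n - i + 1L)))) {
      if (seq_key(toks[i:(i + len - 1L)]) %in% idx$keys) {
        hit <- len
        break
      }
    }
    if (hit > 0L) {
      out <- rbind(out, data.frame(
        record_id = sentence$record_id,
        phrase = paste(toks[i:(i + hit - 1L)], collapse = ""),
        start = i - 1L, end = i + hit - 1L,
        components = paste(seq(i, i + hit - 1L) - 1L, collapse = ","),
        stringsAsFactors = FALSE))
      i <- i + hit
    } else {
      i <- i + 1L
    }
  }
  out
}

# maximal-matching segmentation; returns data.frame(start, end, in_dict)
mm_segment <- function(toks, idx, reverse = FALSE) {
  n <- length(toks)
  segs <- data.frame(start = integer(0), end = integer(0),
                     in_dict = logical(0))
  if (n == 0L) return(segs)
  if (!reverse) {
    i <- 1L
    while (i <= n) {
      hit <- 1L; in_dict <- FALSE
      for (len in rev(seq_len(min(idx$max_len, n - i + 1L)))) {
        if (seq_key(toks[i:(i + len - 1L)]) %in% idx$keys) {
          hit <- len; in_dict <- TRUE
          break
        }
      }
      segs <- rbind(segs, data.frame(start = i, end = i + hit - 1L,
                                     in_dict = in_dict))
      i <- i + hit
    }
  } else {
    j <- n
    while (j >= 1L) {
      hit <- 1L; in_dict <- FALSE
      for (len in rev(seq_len(min(idx$max_len, j)))) {
        if (seq_key(toks[(j - len + 1L):j]) %in% idx$keys) {
          hit <- len; in_dict <- TRUE
          break
        }
      }
      segs <- rbind(data.frame(start = j - hit + 1L, end = j,
                               in_dict = in_dict), segs)
      j <- j - hit
    }
  }
  segs
}

#' @rdname baselines
#' @export
baseline_bdmm <- function(sentence, dictionary) {
  stopifnot(inherits(sentence, "tokenized_sentence"))
  idx <- dict_index(dictionary)
  toks <- sentence$tokens
  if (length(toks) == 0L) return(empty_extractions())
  fwd <- mm_segment(toks, idx, reverse = FALSE)
  rev_ <- mm_segment(toks, idx, reverse = TRUE)
  n_single <- function(s) sum(s$end == s$start)
  chosen <- if (nrow(rev_) < nrow(fwd)) rev_
            else if (nrow(fwd) < nrow(rev_)) fwd
            else if (n_single(rev_) < n_single(fwd)) rev_
            else fwd
  hits <- chosen[chosen$in_dict, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_extractions())
  do.call(rbind, lapply(seq_len(nrow(hits)), function(r) {
    a <- hits$start[r]; b <- hits$end[r]
    data.frame(record_id = sentence$record_id,
               phrase = paste(toks[a:b], collapse = ""),
               start = a - 1L, end = b,
               components = paste(seq(a, b) - 1L, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
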