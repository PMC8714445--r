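#' Intersection-over-union between two phrase strings
#'
#' Similarity of two strings as the character-multiset intersection size
#' divided by the multiset union size. Two empty strings have IoU 1.
#'
#' @param a,b Strings.
#' @return Real in \eqn{[0, 1]}.
#' @examples
#' string_iou("abc", "abd")  # 0.5
#' @export
string_iou <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) == 0L && length(cb) == 0L) return(1)
  chars <- union(ca, cb)
  ta <- table(factor(ca, levels = chars))
  tb <- table(factor(cb, levels = chars))
  sum(pmin(ta, tb)) / sum(pmax(ta, tb))
}

#' Match extractions to gold phrases and count TP/FP/FN
#'
#' Greedy one-to-one matching in descending IoU order: each extraction and
#' each gold phrase is used at most once, a pair counts as a true positive
#' when its IoU reaches `epsilon` (the comparison is `>=`, so `epsilon = 1`
#' demands exact multiset equality rather than failing every match).
#' Unmatched extractions are false positives; unmatched gold phrases are
#' false negatives. IoU ties are broken on the phrase strings themselves,
#' which makes the counts invariant to input ordering.
#'
#' @param extracted Character vector of extracted phrase strings.
#' @param gold Character vector of gold phrase strings.
#' @param epsilon IoU threshold in \eqn{[0, 1]}.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
match_and_count <- function(extracted, gold, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  ne <- length(extracted); ng <- length(gold)
  if (ne == 0L || ng == 0L) {
    return(c(tp = 0L, fp = ne, fn = ng))
  }
  pairs <- expand.grid(e = seq_len(ne), g = seq_len(ng))
  pairs$iou <- mapply(function(i, j) string_iou(extracted[i], gold[j]),
                      pairs$e, pairs$g)
  pairs <- pairs[pairs$iou >= epsilon, , drop = FALSE]
  pairs <- pairs[order(-pairs$iou, extracted[pairs$e], gold[pairs$g]), ,
                 drop = FALSE]
  used_e <- logical(ne); used_g <- logical(ng)
  tp <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$e[r]; j <- pairs$g[r]
    if (used_e[i] || used_g[j]) next
    used_e[i] <- TRUE; used_g[j] <- TRUE
    tp <- tp + 1L
  }
  c(tp = tp, fp = ne - tp, fn = ng - tp)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator for ", what, "; defining the rate as 0",
            call. = FALSE)
    return(0)
  }
  num / den
}

f1_of <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Micro/macro evaluation of extractions against gold annotations
#'
#' Computes per-record TP/FP/FN with [match_and_count()], then
#' micro-averaged precision/recall/F1 from the pooled counts and
#' macro-averaged precision/recall as the plain average of per-record rates
#' over the record set, with the macro F1 as the harmonic mean of macro
#' precision and recall. All rates are percentages. The record set is the
#' union of record ids appearing in either table.
#'
#' @param extractions data.frame with columns `record_id`, `phrase` (as
#'   produced by [extract_corpus()]).
#' @param gold data.frame with columns `record_id`, `phrase`.
#' @param epsilon IoU threshold (scalar).
#' @return Object of class `eval_report`: list with `epsilon`, `per_record`
#'   (data.frame of counts and rates), `totals`, `micro`, `macro`.
#' @export
evaluate_extractions <- function(extractions, gold, epsilon = 0.6) {
  records <- union(unique(gold$record_id), unique(extractions$record_id))
  if (length(records) == 0L) stop_config("no records to evaluate")
  per <- do.call(rbind, lapply(records, function(rid) {
    cnt <- match_and_count(
      extractions$phrase[extractions$record_id == rid],
      gold$phrase[gold$record_id == rid], epsilon)
    data.frame(record_id = rid, tp = cnt[["tp"]], fp = cnt[["fp"]],
               fn = cnt[["fn"]])
  }))
  per$p_s <- ifelse(per$tp + per$fp == 0, 0, per$tp / (per$tp + per$fp)) * 100
  per$r_s <- ifelse(per$tp + per$fn == 0, 0, per$tp / (per$tp + per$fn)) * 100
  nz <- sum(per$tp + per$fp == 0) + sum(per$tp + per$fn == 0)
  if (nz > 0) {
    warning(nz, " per-record rate(s) had a zero denominator; defined as 0",
            call. = FALSE)
  }
  totals <- c(tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn))
  micro_p <- safe_ratio(totals[["tp"]], totals[["tp"]] + totals[["fp"]],
                        "micro precision") * 100
  micro_r <- safe_ratio(totals[["tp"]], totals[["tp"]] + totals[["fn"]],
                        "micro recall") * 100
  macro_p <- mean(per$p_s)
  macro_r <- mean(per$r_s)
  structure(list(
    epsilon = epsilon,
    per_record = per,
    totals = totals,
    micro = c(precision = micro_p, recall = micro_r,
              f1 = f1_of(micro_p, micro_r)),
    macro = c(precision = macro_p, recall = macro_r,
              f1 = f1_of(macro_p, macro_r))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> epsilon = %.2f, %d records (TP %d / FP %d / FN %d)\n",
              x$epsilon, nrow(x$per_record), x$totals[["tp"]],
              x$totals[["fp"]], x$totals[["fn"]]))
  cat(sprintf("  micro  P %6.2f  R %6.2f  F1 %6.2f\n",
              x$micro[["precision"]], x$micro[["recall"]], x$micro[["f1"]]))
  cat(sprintf("  macro  P %6.2f  R %6.2f  F1 %6.2f\n",
              x$macro[["precision"]], x$macro[["recall"]], x$macro[["f1"]]))
  invisible(x)
}
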