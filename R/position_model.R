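#' Per-component BIES position statistics
#'
#' For every component observed in the annotated dictionary we count how
#' many times it occurs at each BIES position. The counts of a component are
#' modelled as a multinomial distribution \eqn{(n, \pi_B, \pi_I, \pi_E,
#' \pi_S)} whose parameters are the maximum-likelihood estimates
#' \eqn{\pi_X = n_X / n}. Counts are stored exactly as integers;
#' probabilities are derived on demand, so a position never observed for a
#' component has probability exactly 0 (no smoothing) and is not a
#' permissible label for it during recognition.
#'
#' @param annotated List of `annotated_phrase` objects (from
#'   [annotate_bies()] / [annotate_dictionary()]); must be non-empty.
#' @return An object of class `position_stats`: an integer matrix with one
#'   row per component and columns `B`, `I`, `E`, `S` (row names are the
#'   components).
#' @examples
#' d <- list(symptom_phrase("a b c", c("a", "b", "c")),
#'           symptom_phrase("a c", c("a", "c")))
#' ps <- position_stats(annotate_dictionary(d))
#' position_probabilities(ps, "a")  # pi_B = 1
#' @export
position_stats <- function(annotated) {
  if (length(annotated) == 0L) {
    stop_config("cannot estimate position statistics from an empty dictionary")
  }
  comps <- unlist(lapply(annotated, function(a) a$phrase$components),
                  use.names = FALSE)
  labs <- unlist(lapply(annotated, function(a) a$labels), use.names = FALSE)
  stopifnot(length(comps) == length(labs))
  labs <- factor(labs, levels = BIES_LEVELS)
  tab <- table(factor(comps, levels = unique(comps)), labs)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), BIES_LEVELS))
  structure(counts, class = c("position_stats", class(counts)))
}

BIES_LEVELS <- c("B", "I", "E", "S")

#' @export
print.position_stats <- function(x, ...) {
  cat(sprintf("<position_stats> %d components, %d position observations\n",
              nrow(x), sum(x)))
  print(head(unclass(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Multinomial MLE position probabilities
#'
#' @param stats A `position_stats` object.
#' @param component Optional component name; if omitted, the full
#'   probability matrix is returned.
#' @return Named numeric vector `(B, I, E, S)` summing to 1, or a matrix of
#'   such rows.
#' @export
position_probabilities <- function(stats, component = NULL) {
  stopifnot(inherits(stats, "position_stats"))
  if (!is.null(component)) {
    if (!component %in% rownames(stats)) stop_oov(component)
    cnt <- stats[component, , drop = TRUE]
    n <- sum(cnt)
    if (n < 1L) stop("component has no position observations: ", component)
    return(cnt / n)
  }
  n <- rowSums(stats)
  sweep(unclass(stats), 1L, n, "/")
}

#' Number of position trials for a component
#'
#' @inheritParams position_probabilities
#' @return Integer total count \eqn{n}.
#' @export
position_trials <- function(stats, component) {
  stopifnot(inherits(stats, "position_stats"))
  if (!component %in% rownames(stats)) stop_oov(component)
  sum(stats[component, ])
}

# probability of one position for one component; 0 for unseen components
pi_of <- function(stats, component, label) {
  if (!component %in% rownames(stats)) return(0)
  cnt <- stats[component, , drop = TRUE]
  unname(cnt[[label]] / sum(cnt))
}

#' Read/write position statistics as TSV
#'
#' Plain-text persistence: columns `component`, `n_B`, `n_I`, `n_E`, `n_S`.
#'
#' @param stats A `position_stats` object.
#' @param path Output (or input) TSV path.
#' @return `read_position_stats()` returns a `position_stats` object;
#'   `write_position_stats()` returns `path` invisibly.
#' @export
write_position_stats <- function(stats, path) {
  stopifnot(inherits(stats, "position_stats"))
  df <- data.frame(component = rownames(stats),
                   n_B = stats[, "B"], n_I = stats[, "I"],
                   n_E = stats[, "E"], n_S = stats[, "S"])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_position_stats
#' @export
read_position_stats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  counts <- as.matrix(df[, c("n_B", "n_I", "n_E", "n_S")])
  dimnames(counts) <- list(df$component, BIES_LEVELS)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("position_stats", class(counts)))
}
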