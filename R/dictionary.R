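#' Symptom phrases and automatic BIES annotation
#'
#' A symptom dictionary is a list of standard phrases used by practitioners.
#' Each phrase is represented as an ordered sequence of \emph{components}:
#' tokenizer-produced words (`granularity = "word"`) or single characters
#' (`granularity = "character"`). Because a standard phrase is known to be a
#' complete symptom mention, its components can be position-annotated
#' automatically with the BIES scheme: a one-component phrase is `S`
#' (Single); a longer phrase starts with `B` (Begin), ends with `E` (End),
#' and every interior component is `I` (Intermediate).
#'
#' @param raw Original phrase string.
#' @param components Character vector of components (non-empty).
#' @param granularity `"word"` or `"character"`.
#' @return `symptom_phrase()` returns an object of class `symptom_phrase`
#'   with fields `raw`, `components`, `granularity`.
#' @examples
#' p <- symptom_phrase("persistent lowback pain",
#'                     c("persistent", "lowback", "pain"), "word")
#' annotate_bies(p)$labels  # "B" "I" "E"
#' @export
symptom_phrase <- function(raw, components, granularity = c("word", "character")) {
  granularity <- match.arg(granularity)
  if (length(components) < 1L || !all(nzchar(components))) {
    stop("a symptom phrase needs at least one non-empty component")
  }
  structure(
    list(raw = raw, components = as.character(components),
         granularity = granularity),
    class = "symptom_phrase"
  )
}

#' @export
print.symptom_phrase <- function(x, ...) {
  cat(sprintf("<symptom_phrase> %s [%s: %s]\n", x$raw, x$granularity,
              paste(x$components, collapse = " | ")))
  invisible(x)
}

#' Load a symptom dictionary
#'
#' Reads one standard phrase per line from a UTF-8 text file, strips
#' punctuation, tokenizes each phrase into components, and removes
#' duplicates. Deduplication acts on the tokenized component sequence (two
#' raw strings with identical components carry identical evidence); the
#' order of first occurrence is preserved.
#'
#' @param path Path to the dictionary file (one phrase per line).
#' @param granularity `"word"` (tokenizer-produced components) or
#'   `"character"` (one component per character).
#' @param tokenizer Function mapping a string to a token vector; used only
#'   for word granularity. Defaults to [whitespace_tokenizer()].
#' @param punct_class Regex character class of punctuation to strip before
#'   tokenization (default POSIX punctuation).
#' @return List of [symptom_phrase()] objects.
#' @export
load_dictionary <- function(path, granularity = c("word", "character"),
                            tokenizer = whitespace_tokenizer,
                            punct_class = "[[:punct:]]") {
  granularity <- match.arg(granularity)
  if (!file.exists(path)) stop("cannot read dictionary file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  phrases <- parse_dictionary_lines(lines, granularity, tokenizer, punct_class)
  if (length(phrases) == 0L) {
    stop_config("dictionary is empty after filtering: ", path)
  }
  phrases
}

parse_dictionary_lines <- function(lines, granularity, tokenizer, punct_class) {
  phrases <- list()
  seen <- new.env(parent = emptyenv())
  for (line in lines) {
    raw <- trimws(line)
    if (!nzchar(raw)) next
    clean <- strip_punctuation(raw, punct_class)
    comps <- if (granularity == "character") character_tokenizer(clean)
             else tokenizer(clean)
    comps <- comps[nzchar(comps)]
    if (length(comps) == 0L) next
    key <- paste(comps, collapse = "")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    phrases[[length(phrases) + 1L]] <- symptom_phrase(raw, comps, granularity)
  }
  phrases
}

#' Automatically annotate a phrase with BIES labels
#'
#' Annotation depends only on the component count: a single component is
#' `S`; otherwise the first component is `B`, the last is `E`, and all
#' interior components are `I`.
#'
#' @param phrase A [symptom_phrase()].
#' @return An object of class `annotated_phrase`: list with `phrase` and
#'   `labels` (character vector over `B`, `I`, `E`, `S`, same length as the
#'   components).
#' @export
annotate_bies <- function(phrase) {
  stopifnot(inherits(phrase, "symptom_phrase"))
  m <- length(phrase$components)
  labels <- if (m == 1L) "S" else c("B", rep("I", m - 2L), "E")
  structure(list(phrase = phrase, labels = labels), class = "annotated_phrase")
}

#' @export
print.annotated_phrase <- function(x, ...) {
  cat(sprintf("<annotated_phrase> %s\n",
              paste(sprintf("%s/%s", x$phrase$components, x$labels),
                    collapse = " ")))
  invisible(x)
}

#' Annotate a whole dictionary
#'
#' @param phrases List of [symptom_phrase()] objects.
#' @return List of `annotated_phrase` objects.
#' @export
annotate_dictionary <- function(phrases) {
  lapply(phrases, annotate_bies)
}
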