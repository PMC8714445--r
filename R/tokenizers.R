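#' Tokenizer contract
#'
#' A tokenizer is any function mapping a single string to an ordered
#' character vector of tokens. The method itself is tokenizer-agnostic:
#' segmentation of real Chinese text is delegated to an external tool, and
#' any such tool can be plugged in wherever a `tokenizer` argument appears.
#' Two reference tokenizers are provided: [whitespace_tokenizer()] for
#' pre-segmented (or synthetic) text and [character_tokenizer()] for
#' character-granularity analysis.
#'
#' @param x A length-one character string.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' whitespace_tokenizer("persistent low-back pain")
#' character_tokenizer("abc")
#' @name tokenizers
NULL

#' @rdname tokenizers
#' @export
whitespace_tokenizer <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  out <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  out[nzchar(out)]
}

#' @rdname tokenizers
#' @export
character_tokenizer <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("[[:space:]]", "", x)
  if (!nzchar(x)) return(character())
  strsplit(x, "")[[1]]
}

# strip Unicode punctuation (configurable class, default [[:punct:]] which in
# a UTF-8 locale covers the common Chinese punctuation as well)
strip_punctuation <- function(x, punct_class = "[[:punct:]]") {
  gsub(punct_class, "", x, perl = TRUE)
}
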