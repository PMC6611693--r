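#' Tokenize text on non-alphanumeric boundaries
#'
#' Splits text into tokens wherever a run of non-alphanumeric characters
#' occurs. Tokens are returned in order; empty tokens are dropped. This is
#' the single tokenizer used by both the concept recognizer and the topic
#' preprocessing pipeline, so token spans are comparable between the two.
#'
#' @param text Character scalar (or vector; vectors return a list).
#' @param lowercase Lowercase tokens after splitting.
#' @return Character vector of tokens (list of such for vector input).
#' @export
#' @examples
#' tokenize("Treating type-2 diabetes, fast.")
tokenize <- function(text, lowercase = FALSE) {
  if (length(text) == 1L) {
    return(.tokenize1(text, lowercase))
  }
  lapply(text, .tokenize1, lowercase = lowercase)
}

.tokenize1 <- function(text, lowercase) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(text, "[^[:alnum:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (lowercase) toks <- tolower(toks)
  toks
}
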