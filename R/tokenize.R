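#' Tokenize text
#'
#' Lowercases and splits on any character that is not a Unicode letter or
#' digit; empty tokens are dropped. Numbers are kept as tokens because
#' chemical names fragment into digit runs and discarding them loses
#' discriminative content.
#'
#' @param text Character vector; elements are tokenized independently and
#'   concatenated.
#' @return Character vector of lowercase tokens.
#' @examples
#' tokenize("Pyrimidine-2,4-diamine derivatives!")
#' @export
tokenize <- function(text) {
  if (!length(text)) return(character())
  toks <- unlist(strsplit(tolower(text), "[^\\p{L}\\p{N}]+", perl = TRUE),
                 use.names = FALSE)
  toks[nzchar(toks)]
}

#' Minimal English stopword list
#'
#' The default stopword set used at indexing and query time: roughly 120
#' high-frequency English function words. Deliberately small; a custom
#' list can be passed to [index_config()].
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c(
    "a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each",
    "few", "for", "from", "further", "had", "has", "have", "having",
    "he", "her", "here", "hers", "him", "his", "how", "i", "if", "in",
    "into", "is", "it", "its", "itself", "just", "more", "most", "my",
    "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or",
    "other", "our", "ours", "out", "over", "own", "said", "same", "she",
    "should", "so", "some", "such", "than", "that", "the", "their",
    "theirs", "them", "then", "there", "these", "they", "this", "those",
    "through", "to", "too", "under", "until", "up", "very", "was", "we",
    "were", "what", "when", "where", "which", "while", "who", "whom",
    "why", "will", "with", "would", "you", "your", "yours", "also",
    "may", "might", "must", "shall", "such", "thereof", "wherein",
    "herein", "thereby", "whereby", "therein"
  )
}

# shared text-side processing: tokenize, stopword-filter, stem
process_text_tokens <- function(text, stopwords = default_stopwords(),
                                min_token_length = 1L) {
  toks <- tokenize(text)
  toks <- toks[!(toks %in% stopwords) & nchar(toks) >= min_token_length]
  stem_tokens(toks)
}
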