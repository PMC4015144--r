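#' Annotate a token sequence with terminology concepts
#'
#' Greedy leftmost-longest non-overlapping dictionary matching: at each
#' position the longest terminology term starting there is matched (terms
#' are tokenized with [tokenize()], the same tokenizer that produced the
#' input); after a match, scanning resumes at the token following the
#' match. Matching is exact on lowercased tokens — no stemming, no fuzzy
#' matching — so the process is deterministic and auditable.
#'
#' @param tokens Character vector of lowercase tokens.
#' @param term A [terminology()].
#' @return data.frame with columns `source`, `concept_id`, `start`, `end`
#'   (token offsets, 0-based, end exclusive); zero rows when nothing
#'   matches.
#' @export
annotate_text <- function(tokens, term) {
  empty <- data.frame(source = character(), concept_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!length(tokens) || !nrow(term$entries)) return(empty)
  keys <- vapply(term$entries$term,
                 function(t) paste(tokenize(t), collapse = " "), "")
  keep <- nzchar(keys) & !duplicated(keys)
  lookup <- stats::setNames(seq_len(nrow(term$entries))[keep], keys[keep])
  max_len <- max(lengths(strsplit(names(lookup), " ", fixed = TRUE)))
  n <- length(tokens)
  out_src <- character(); out_cid <- character()
  out_start <- integer(); out_end <- integer()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      phrase <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      row <- unname(lookup[phrase])
      if (!is.na(row)) {
        out_src <- c(out_src, term$entries$source[[row]])
        out_cid <- c(out_cid, term$entries$concept_id[[row]])
        out_start <- c(out_start, i - 1L)
        out_end <- c(out_end, i - 1L + len)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  data.frame(source = out_src, concept_id = out_cid,
             start = out_start, end = out_end, stringsAsFactors = FALSE)
}

#' Normalize a corpus against terminologies
#'
#' Runs dictionary normalization over each document's scoped text
#' ([extract_field_text()] with `"TAC"` or `"TACD"`) for every
#' terminology, and stores the union of the resulting concept annotations
#' as the document's metadata, tagged with the scope. Concepts are stored
#' as a bag — repeated matches are kept — so the indexed metadata carries
#' term frequencies. Text fields are untouched; re-annotating with the
#' same inputs is idempotent.
#'
#' @param corpus A `patent_corpus`.
#' @param terminologies A single [terminology()] or a list of them.
#'   Overlapping matches from different terminologies are all kept.
#' @param scope `"TAC"` or `"TACD"` — which fields are scanned.
#' @return The corpus with metadata replaced on every document.
#' @export
annotate_corpus <- function(corpus, terminologies, scope = c("TAC", "TACD")) {
  scope <- match.arg(scope)
  if (inherits(terminologies, "terminology")) {
    terminologies <- list(terminologies)
  }
  docs <- lapply(corpus, function(doc) {
    tokens <- tokenize(extract_field_text(doc, scope))
    anns <- lapply(terminologies, function(t) annotate_text(tokens, t))
    anns <- do.call(rbind, anns)
    metadata <- data.frame(source = anns$source, concept_id = anns$concept_id,
                           stringsAsFactors = FALSE)
    attr(metadata, "scope") <- scope
    doc$metadata <- metadata
    doc
  })
  patent_corpus(docs)
}
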