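#' Build a prior-art query from a patent document
#'
#' A prior-art topic is the full title+abstract+claims of the filed
#' patent; the query bag is its processed (tokenized, stopword-filtered,
#' stemmed) tokens with their occurrence counts. The description never
#' enters the query.
#'
#' @param doc A `patent_document`.
#' @param config An [index_config()]; supplies the stopword list and
#'   minimum token length so query-side processing matches the index.
#' @return A [patent_query()].
#' @export
build_prior_art_query <- function(doc, config = index_config()) {
  toks <- process_text_tokens(extract_field_text(doc, "TAC"),
                              stopwords = config$stopword_list,
                              min_token_length = config$min_token_length)
  if (!length(toks)) {
    stop("patent ", doc$patent_id, " has no usable TAC text for a query")
  }
  patent_query(toks)
}

#' Build an ad-hoc keyword query
#'
#' @param keywords Query text (a few keywords or sentences).
#' @param config An [index_config()] supplying the stopword list.
#' @return A [patent_query()].
#' @export
build_adhoc_query <- function(keywords, config = index_config()) {
  toks <- process_text_tokens(keywords,
                              stopwords = config$stopword_list,
                              min_token_length = config$min_token_length)
  if (!length(toks)) stop("query is empty after processing")
  patent_query(toks)
}

#' Normalize an IPC code into index/query tokens
#'
#' Uppercases and removes internal whitespace, then emits two
#' pseudo-tokens: the 4-character subclass prefix (e.g. `IPC_C07D`) and
#' the full compacted code (e.g. `IPC_C07D239/47`). The subclass token
#' lets patents match at the classification-family level even when the
#' main groups differ.
#'
#' @param raw Raw IPC code string, e.g. `"C07D 239/47"`.
#' @return Character vector of one or two `IPC_` tokens (one when the
#'   code is exactly a subclass).
#' @export
normalize_ipc_code <- function(raw) {
  compact <- toupper(gsub("[[:space:]]+", "", raw))
  if (nchar(compact) < 4L) {
    stop("IPC code too short after compaction: '", raw, "'")
  }
  unique(c(paste0("IPC_", substr(compact, 1L, 4L)),
           paste0("IPC_", compact)))
}

#' Add IPC codes to a query
#'
#' Appends the `IPC_` tokens of the given codes to the query with query
#' term frequency 1 each (deduplicated); existing terms are unchanged.
#'
#' @param query A [patent_query()].
#' @param codes Character vector of raw IPC codes (may be empty).
#' @return The augmented [patent_query()].
#' @export
augment_query_with_ipc <- function(query, codes) {
  if (!length(codes)) return(query)
  ipc <- unique(unlist(lapply(codes, normalize_ipc_code), use.names = FALSE))
  qtf <- unclass(query)
  new <- setdiff(ipc, names(qtf))
  structure(c(qtf, stats::setNames(rep(1L, length(new)), new)),
            class = "patent_query")
}

#' In-collection citation counts
#'
#' For each corpus patent, the number of distinct other corpus patents
#' citing it. Self-citations and citations to or from outside the corpus
#' contribute nothing.
#'
#' @param corpus A `patent_corpus`.
#' @return Object of class `citation_table`: named integer vector over
#'   all corpus ids.
#' @export
compute_citation_counts <- function(corpus) {
  ids <- corpus_ids(corpus)
  counts <- stats::setNames(integer(length(ids)), ids)
  for (doc in corpus) {
    targets <- unique(doc$cited_ids)
    targets <- targets[targets %in% ids & targets != doc$patent_id]
    counts[targets] <- counts[targets] + 1L
  }
  structure(counts, class = "citation_table")
}

#' Re-rank a result list with co-citation counts
#'
#' Linearly combines the retrieval score with a citation-popularity
#' score, both min-max normalized within the retrieved list:
#' `final = (1 - alpha) * s_ir + alpha * s_cit`, where `s_cit` is the
#' (optionally log-damped) in-collection citation count. When either
#' component is constant across the list its normalized form is all
#' zero. The operation is a permutation of the input list — no document
#' is added or removed — re-sorted by (final score desc, doc id asc).
#'
#' @param ranked A `ranked_results`.
#' @param table A [compute_citation_counts()] table; documents absent
#'   from it count 0.
#' @param alpha Weight of the citation component in `[0, 1]` (default
#'   0.2); `alpha = 0` returns the input ordering.
#' @param damping `"log1p"` (default; citation counts are heavy-tailed
#'   and raw counts would dominate min-max scaling) or `"none"`.
#' @return A `ranked_results` with combined scores.
#' @export
rerank_with_citations <- function(ranked, table, alpha = 0.2,
                                  damping = c("log1p", "none")) {
  damping <- match.arg(damping)
  stopifnot(alpha >= 0, alpha <= 1)
  if (!nrow(ranked)) return(ranked)
  minmax <- function(x) {
    rng <- range(x)
    if (rng[[1L]] == rng[[2L]]) return(rep(0, length(x)))
    (x - rng[[1L]]) / (rng[[2L]] - rng[[1L]])
  }
  cit <- as.numeric(unclass(table)[ranked$doc_id])
  cit[is.na(cit)] <- 0
  if (damping == "log1p") cit <- log1p(cit)
  final <- (1 - alpha) * minmax(ranked$score) + alpha * minmax(cit)
  ord <- order(-final, ranked$doc_id, method = "radix")
  ranked_results(data.frame(doc_id = ranked$doc_id[ord],
                            score = final[ord], stringsAsFactors = FALSE),
                 query_id = attr(ranked, "query_id"))
}

#' Run a full search strategy over a topic set
#'
#' For each topic: builds the query (prior-art topics use the source
#' patent's TAC text, ad-hoc topics their keyword text), optionally
#' augments it with the topic's IPC codes, retrieves, optionally
#' re-ranks with co-citation counts, and — for prior-art topics —
#' optionally removes the topic's own source patent from the results
#' (which trivially matches itself).
#'
#' @param index An `inverted_index` over `corpus`.
#' @param corpus The `patent_corpus` behind the index (needed for topic
#'   source patents and citation counts).
#' @param topics List of topics from [build_prior_art_benchmark()],
#'   [build_known_item_benchmark()] or [read_topics()].
#' @param params A [ranking_params()].
#' @param ipc_boost Logical; add topic IPC codes to the query.
#' @param rerank_alpha `NULL` for no re-ranking, else the citation weight
#'   passed to [rerank_with_citations()].
#' @param rerank_damping Damping for re-ranking (`"log1p"` or `"none"`).
#' @param exclude_self Logical; drop the source patent from its own
#'   prior-art result list (default `TRUE`).
#' @param tag Run tag written to run files.
#' @return A run: data.frame with columns `topic_id`, `doc_id`, `rank`
#'   (0-based), `score`, `tag`, class `trec_run`.
#' @export
run_search <- function(index, corpus, topics, params = ranking_params(),
                       ipc_boost = FALSE, rerank_alpha = NULL,
                       rerank_damping = "log1p", exclude_self = TRUE,
                       tag = "patret") {
  cit_table <- if (!is.null(rerank_alpha)) compute_citation_counts(corpus)
  rows <- lapply(topics, function(topic) {
    if (topic$kind == "PA") {
      doc <- corpus[[topic$source_patent_id]]
      if (is.null(doc)) {
        stop("topic ", topic$topic_id, " references unknown patent ",
             topic$source_patent_id)
      }
      query <- build_prior_art_query(doc, index$config)
    } else {
      query <- build_adhoc_query(topic$query_text, index$config)
    }
    if (ipc_boost) query <- augment_query_with_ipc(query, topic$ipc_codes)
    ranked <- retrieve(index, query, params, query_id = topic$topic_id)
    if (!is.null(rerank_alpha)) {
      ranked <- rerank_with_citations(ranked, cit_table,
                                      alpha = rerank_alpha,
                                      damping = rerank_damping)
    }
    if (topic$kind == "PA" && exclude_self) {
      ranked <- ranked[ranked$doc_id != topic$source_patent_id, ,
                       drop = FALSE]
    }
    if (!nrow(ranked)) return(NULL)
    data.frame(topic_id = topic$topic_id, doc_id = ranked$doc_id,
               rank = seq_len(nrow(ranked)) - 1L, score = ranked$score,
               tag = tag, stringsAsFactors = FALSE)
  })
  run <- do.call(rbind, rows)
  if (is.null(run)) {
    run <- data.frame(topic_id = character(), doc_id = character(),
                      rank = integer(), score = numeric(),
                      tag = character(), stringsAsFactors = FALSE)
  }
  rownames(run) <- NULL
  structure(run, class = c("trec_run", "data.frame"))
}
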