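#' Construct a benchmark topic
#'
#' @param topic_id Unique topic identifier.
#' @param kind `"PA"` (prior art: the topic is a source patent whose TAC
#'   text becomes the query), `"TS"` (technical survey: short keyword
#'   query) or `"KI"` (known-item: keyword query with exactly one
#'   relevant patent).
#' @param query_text Keyword text for TS/KI topics.
#' @param source_patent_id Source patent id for PA topics.
#' @param ipc_codes IPC codes attached to the topic (possibly empty).
#' @return Object of class `patent_topic`.
#' @export
patent_topic <- function(topic_id, kind = c("PA", "TS", "KI"),
                         query_text = NULL, source_patent_id = NULL,
                         ipc_codes = character()) {
  kind <- match.arg(kind)
  if (kind == "PA" && is.null(source_patent_id)) {
    stop("PA topics need a source_patent_id")
  }
  if (kind != "PA" && (is.null(query_text) || !nzchar(query_text))) {
    stop(kind, " topics need query_text")
  }
  structure(list(topic_id = topic_id, kind = kind,
                 query_text = query_text,
                 source_patent_id = source_patent_id,
                 ipc_codes = as.character(ipc_codes)),
            class = "patent_topic")
}

new_qrels <- function(lst) structure(lst, class = "qrels")

#' Build a prior-art benchmark from a corpus
#'
#' Candidate topics are the patents citing at least one other patent
#' present in the corpus; `n_topics` of them are sampled uniformly
#' without replacement. The relevance judgments of a topic are its
#' cited patents restricted to the corpus — patents cited but not in the
#' collection cannot be retrieved and are excluded — and never include
#' the source patent itself. The topic carries the source patent's IPC
#' codes for optional query augmentation.
#'
#' @param corpus A `patent_corpus`.
#' @param n_topics Number of topics to sample; if fewer candidates
#'   exist, all are used with a warning.
#' @param seed Integer seed; the sample is a pure function of (corpus,
#'   parameters, seed).
#' @return List with `topics` (list of [patent_topic()]) and `qrels`
#'   (named list: topic id to character vector of relevant ids).
#' @export
build_prior_art_benchmark <- function(corpus, n_topics = 50L, seed = 42L) {
  ids <- corpus_ids(corpus)
  rel_of <- lapply(corpus, function(doc) {
    r <- unique(doc$cited_ids)
    r[r %in% ids & r != doc$patent_id]
  })
  candidates <- ids[lengths(rel_of) > 0L]
  if (!length(candidates)) {
    stop("no patent cites another patent present in the corpus")
  }
  if (length(candidates) < n_topics) {
    warning("only ", length(candidates), " candidate topics available; ",
            "using all of them")
    chosen <- candidates
  } else {
    set.seed(seed)
    chosen <- candidates[sort(sample.int(length(candidates), n_topics))]
  }
  topics <- lapply(chosen, function(id) {
    patent_topic(paste0("PA-", id), "PA", source_patent_id = id,
                 ipc_codes = corpus[[id]]$ipc_codes)
  })
  qrels <- stats::setNames(rel_of[chosen], paste0("PA-", chosen))
  list(topics = topics, qrels = new_qrels(qrels))
}

#' Build a known-item benchmark from a corpus
#'
#' Each topic is `words_per_topic` distinct words sampled uniformly from
#' the eligible words of one patent's title/abstract/claims text —
#' lowercased tokens with stopwords removed and at least two characters,
#' a filter that prevents degenerate all-stopword topics — and its only
#' relevant document is that source patent. Patents with too few
#' eligible words are skipped.
#'
#' @param corpus A `patent_corpus`.
#' @param n_topics Number of topics; capped (with a warning) at the
#'   number of eligible patents.
#' @param words_per_topic Words per topic (default 10).
#' @param seed Integer seed.
#' @param stopwords Stopword list used by the eligibility filter.
#' @return List with `topics` and `qrels` (each topic maps to exactly
#'   its source patent).
#' @export
build_known_item_benchmark <- function(corpus, n_topics = 100L,
                                       words_per_topic = 10L, seed = 42L,
                                       stopwords = default_stopwords()) {
  ids <- corpus_ids(corpus)
  eligible <- lapply(corpus, function(doc) {
    toks <- unique(tokenize(extract_field_text(doc, "TAC")))
    toks[!(toks %in% stopwords) & nchar(toks) >= 2L]
  })
  ok <- ids[lengths(eligible) >= words_per_topic]
  if (!length(ok)) stop("no patent has enough eligible words")
  set.seed(seed)
  if (length(ok) < n_topics) {
    warning("only ", length(ok), " eligible patents; using all of them")
    chosen <- ok
  } else {
    chosen <- ok[sort(sample.int(length(ok), n_topics))]
  }
  topics <- lapply(chosen, function(id) {
    words <- sample(eligible[[id]], words_per_topic)
    patent_topic(paste0("KI-", id), "KI",
                 query_text = paste(words, collapse = " "),
                 ipc_codes = corpus[[id]]$ipc_codes)
  })
  qrels <- stats::setNames(lapply(chosen, identity), paste0("KI-", chosen))
  list(topics = topics, qrels = new_qrels(qrels))
}

#' Write topics to the topics XML dialect
#'
#' @param topics List of [patent_topic()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_topics <- function(topics, path) {
  root <- xml2::xml_new_root("topics")
  for (topic in topics) {
    node <- xml2::xml_add_child(root, "topic", id = topic$topic_id,
                                kind = topic$kind)
    if (topic$kind == "PA") {
      xml2::xml_add_child(node, "source", topic$source_patent_id)
    } else {
      xml2::xml_add_child(node, "query", topic$query_text)
    }
    for (code in topic$ipc_codes) xml2::xml_add_child(node, "ipc", code)
  }
  xml2::write_xml(root, path, encoding = "UTF-8")
  invisible(path)
}

#' Read topics from the topics XML dialect
#'
#' @param path Path to a topics XML file.
#' @return List of [patent_topic()].
#' @export
read_topics <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "/topics/topic")
  topics <- lapply(nodes, function(node) {
    kind <- xml2::xml_attr(node, "kind")
    src <- xml2::xml_find_first(node, "source")
    qry <- xml2::xml_find_first(node, "query")
    patent_topic(
      topic_id = xml2::xml_attr(node, "id"),
      kind = kind,
      query_text = if (!inherits(qry, "xml_missing")) xml2::xml_text(qry),
      source_patent_id = if (!inherits(src, "xml_missing")) {
        xml2::xml_text(src)
      },
      ipc_codes = xml2::xml_text(xml2::xml_find_all(node, "ipc"))
    )
  })
  tids <- vapply(topics, function(t) t$topic_id, "")
  if (anyDuplicated(tids)) {
    stop("duplicate topic id: ", tids[duplicated(tids)][[1L]])
  }
  topics
}

#' Write qrels in TREC format
#'
#' Lines `qid 0 docid rel` with binary relevance 1. Topics whose
#' relevant set is empty produce no lines (the format cannot represent
#' them).
#'
#' @param qrels A qrels object (named list: topic id to relevant ids).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qrels <- function(qrels, path) {
  lines <- unlist(lapply(names(qrels), function(tid) {
    if (!length(qrels[[tid]])) return(character(0))
    paste(tid, "0", qrels[[tid]], "1")
  }), use.names = FALSE)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read qrels in TREC format
#'
#' Lines `qid 0 docid rel`; documents with `rel > 0` are relevant. A
#' `rel = 0` line records the topic without adding a relevant document.
#'
#' @param path Path to a qrels file.
#' @return A qrels object (named list).
#' @export
read_qrels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    if (length(parts) != 4L || is.na(suppressWarnings(as.numeric(parts[[4L]])))) {
      stop("malformed qrels line ", i, ": '", lines[[i]], "'")
    }
    tid <- parts[[1L]]
    if (is.null(out[[tid]])) out[[tid]] <- character(0)
    if (as.numeric(parts[[4L]]) > 0) {
      out[[tid]] <- unique(c(out[[tid]], parts[[3L]]))
    }
  }
  new_qrels(out)
}

#' Write a run in TREC format
#'
#' Lines `qid Q0 docid rank score tag`; the rank column is 0-based.
#'
#' @param run A `trec_run` data.frame from [run_search()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run <- function(run, path) {
  lines <- paste(run$topic_id, "Q0", run$doc_id, run$rank,
                 format(run$score, digits = 12, trim = TRUE,
                        scientific = FALSE),
                 run$tag)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a run in TREC format
#'
#' The stored rank column is ignored: entries are re-sorted by
#' (topic id, score descending, doc id ascending) and ranks recomputed,
#' so a shuffled file yields the same in-memory ranking.
#'
#' @param path Path to a run file.
#' @return A `trec_run` data.frame.
#' @export
read_run <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(data.frame(topic_id = character(), doc_id = character(),
                                rank = integer(), score = numeric(),
                                tag = character(), stringsAsFactors = FALSE),
                     class = c("trec_run", "data.frame")))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 6L)
  if (length(bad)) stop("malformed run line ", bad[[1L]])
  score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  if (anyNA(score)) {
    stop("non-numeric score on run line ", which(is.na(score))[[1L]])
  }
  df <- data.frame(topic_id = vapply(parts, `[[`, "", 1L),
                   doc_id = vapply(parts, `[[`, "", 3L),
                   score = score,
                   tag = vapply(parts, `[[`, "", 6L),
                   stringsAsFactors = FALSE)
  df <- df[order(df$topic_id, -df$score, df$doc_id, method = "radix"), ]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$topic_id),
                           seq_along), use.names = FALSE) - 1L
  df <- df[, c("topic_id", "doc_id", "rank", "score", "tag")]
  rownames(df) <- NULL
  structure(df, class = c("trec_run", "data.frame"))
}
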